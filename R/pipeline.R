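#' Fit the full training pipeline
#'
#' Convenience wrapper over the whole training side: computes the seven
#' dihedrals and the high-detail pucker pair of every labeled training suite,
#' clusters each pucker-pair set on the torus with [mint_age()], attaches the
#' cluster assignments, and trains the low-detail classifier with
#' [precis_train()].
#'
#' @param suites Training suite tibble with a `conformer` column (and
#'   optionally a precomputed `pucker_pair` column; otherwise the ring
#'   geometry route is used).
#' @param lambda Covariance regularization weight.
#' @param alpha_level,n_boot Mode-hunting settings passed to [mint_age()].
#' @param params Optional named list of [age_params()] per pucker pair;
#'   defaults to [age_defaults()].
#' @return List with `model` (the fitted `rnaprecis_model`), `suites` (the
#'   input augmented with `cluster`) and `clusterings` (per-pair `mint_age`
#'   objects).
#' @export
fit_rnaprecis <- function(suites, lambda = 0.5, alpha_level = 0.005,
                          n_boot = 200, params = NULL) {
  stopifnot("conformer" %in% names(suites))
  if (!all(suite_dihedral_names() %in% names(suites))) {
    suites <- suite_dihedrals(suites)
  }
  if (!"pucker_pair" %in% names(suites)) {
    suites <- suite_pucker_pair(suites, "HD")
    suites$pucker_pair <- suites$pucker_pair_HD
  }
  suites$cluster <- NA_integer_
  clusterings <- list()
  for (pair in unique(suites$pucker_pair)) {
    rows <- which(suites$pucker_pair == pair)
    angs <- as.matrix(suites[rows, suite_dihedral_names()])
    pp <- if (!is.null(params)) params[[pair]] else age_defaults(pair)
    cl <- mint_age(angs, pp, alpha_level = alpha_level, n_boot = n_boot,
                   labels = suites$conformer[rows])
    suites$cluster[rows] <- cl$assignment
    clusterings[[pair]] <- cl
  }
  model <- precis_train(suites, lambda = lambda)
  list(model = model, suites = suites, clusterings = clusterings)
}

#' Rebuild MUCCSS points from flat table columns
#'
#' Reconstructs the `muccss` list-column (and the low-detail gate) from the
#' flat columns written by [run_extract()], so that a predictions run can
#' start from a CSV instead of coordinate files.
#'
#' @param df Tibble with columns `d2`, `d3`, `alpha_mu`, `theta1`, `phi1`,
#'   `theta2`, `phi2` and `pperp5`, `pperp3`.
#' @return The input with `muccss` and `pucker_pair_LD` columns.
#' @export
suites_from_table <- function(df) {
  from_polar <- function(theta, phi) {
    th <- theta * pi / 180; ph <- phi * pi / 180
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  df$muccss <- purrr::pmap(
    df[, c("d2", "d3", "alpha_mu", "theta1", "phi1", "theta2", "phi2")],
    function(d2, d3, alpha_mu, theta1, phi1, theta2, phi2) {
      new_muccss(d2, d3, alpha_mu, from_polar(theta1, phi1),
                 from_polar(theta2, phi2))
    }
  )
  code <- function(d) ifelse(d >= PPERP_CUTOFF, "3", "2")
  df$pucker_pair_LD <- ifelse(
    is.na(df$pperp3), NA_character_,
    paste0("P", code(df$pperp5), code(df$pperp3))
  )
  df
}

#' Extract per-suite geometry from coordinate files
#'
#' Reads each structure file, assembles suites and writes the flat per-suite
#' report (identifiers, the seven dihedrals where computable, Pperp
#' distances, pucker pairs, MUCCSS coordinates). Files that fail to parse are
#' logged and skipped; the run continues.
#'
#' @param paths Character vector of PDB/mmCIF files.
#' @param out Output CSV path.
#' @return The extracted tibble, invisibly.
#' @export
run_extract <- function(paths, out) {
  tabs <- list()
  for (p in paths) {
    tab <- tryCatch({
      suites <- build_suites(read_rna_atoms(p))
      if (nrow(suites) == 0) NULL else extract_table(suites)
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", p, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(tab)) tabs[[length(tabs) + 1]] <- tab
  }
  res <- if (length(tabs)) dplyr::bind_rows(tabs) else extract_table(NULL)
  readr::write_csv(res, out)
  invisible(res)
}

# the flat extract format; dihedrals are NA when the suite lacks atoms
extract_table <- function(suites) {
  if (is.null(suites) || nrow(suites) == 0) {
    out <- tibble::tibble(
      structure_id = character(), chain = character(), resnum = integer(),
      icode = character()
    )
    for (v in c(suite_dihedral_names(), "pperp5", "pperp3")) out[[v]] <- numeric()
    out$pucker_pair_HD <- character(); out$pucker_pair_LD <- character()
    for (v in c("d2", "d3", "alpha_mu", "theta1", "phi1", "theta2", "phi2"))
      out[[v]] <- numeric()
    return(out)
  }
  dih <- purrr::map(suites$atoms, function(at) {
    tryCatch(measure_suite_dihedrals(at$prev, at$curr),
             error = function(e) stats::setNames(rep(NA_real_, 7),
                                                 suite_dihedral_names()))
  })
  hd <- purrr::map_chr(suites$atoms, function(at) {
    tryCatch({
      code <- function(p) if (p$state == "C3_endo") "3" else "2"
      paste0("P", code(pucker_from_nu(at$prev)), code(pucker_from_nu(at$curr)))
    }, error = function(e) NA_character_)
  })
  out <- suites |>
    suite_pperp() |>
    suite_muccss()
  code <- function(d) ifelse(d >= PPERP_CUTOFF, "3", "2")
  dplyr::bind_cols(
    out[, c("structure_id", "chain", "resnum", "icode")],
    tibble::as_tibble(do.call(rbind, dih)),
    out[, c("pperp5", "pperp3")],
    tibble::tibble(
      pucker_pair_HD = hd,
      pucker_pair_LD = ifelse(is.na(out$pperp3), NA_character_,
                              paste0("P", code(out$pperp5), code(out$pperp3)))
    ),
    out[, c("d2", "d3", "alpha_mu", "theta1", "phi1", "theta2", "phi2")]
  )
}

#' Simulate a synthetic gold standard to disk
#'
#' Runs [sample_gold_standard()] and writes the training geometry table with
#' labels, the label CSV, the test answer manifest, and PDB files for the
#' test suites (so the coordinate-reading path can be exercised end to end).
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [synthetic_config()].
#' @return List of written paths, invisibly.
#' @export
run_simulate <- function(out_dir, cfg = synthetic_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- sample_gold_standard(cfg)
  train_tab <- extract_table(gs$train)
  train_tab$conformer <- gs$train$conformer
  paths <- list(
    train = file.path(out_dir, "train_suites.csv"),
    labels = file.path(out_dir, "train_labels.csv"),
    manifest = file.path(out_dir, "test_manifest.csv"),
    test_dir = file.path(out_dir, "test_pdb")
  )
  readr::write_csv(train_tab, paths$train)
  readr::write_csv(
    gs$train[, c("structure_id", "chain", "resnum", "icode", "conformer")],
    paths$labels
  )
  readr::write_csv(gs$manifest, paths$manifest)
  dir.create(paths$test_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(gs$test))) {
    write_suites_pdb(gs$test[i, ],
                     file.path(paths$test_dir,
                               paste0(gs$test$structure_id[i], ".pdb")))
  }
  invisible(paths)
}

#' Train from extracted tables on disk
#'
#' @param train_csv Extract CSV (from [run_extract()] or [run_simulate()])
#'   with a `conformer` column, or accompanied by `labels_csv`.
#' @param out_model Path for the model JSON.
#' @param labels_csv Optional label CSV joined on the suite identifiers.
#' @inheritParams fit_rnaprecis
#' @return The fitted model, invisibly.
#' @export
run_train <- function(train_csv, out_model, labels_csv = NULL, lambda = 0.5,
                      alpha_level = 0.05, n_boot = 200) {
  df <- readr::read_csv(train_csv, show_col_types = FALSE)
  df$icode[is.na(df$icode)] <- ""
  if (!is.null(labels_csv)) {
    lab <- read_label_table(labels_csv)
    df <- dplyr::inner_join(df, lab,
                            by = c("structure_id", "chain", "resnum", "icode"))
  }
  if (!"conformer" %in% names(df)) {
    stop("training table has no conformer labels; supply labels_csv", call. = FALSE)
  }
  df <- suites_from_table(df)
  df$pucker_pair <- df$pucker_pair_HD
  fit <- fit_rnaprecis(df, lambda = lambda, alpha_level = alpha_level,
                       n_boot = n_boot)
  write_model(fit$model, out_model)
  invisible(fit$model)
}

#' Predict conformers for structures on disk
#'
#' @param paths Coordinate files (PDB/mmCIF) of test structures.
#' @param model_path Model JSON from [run_train()] / [write_model()].
#' @param out Output predictions CSV.
#' @return The prediction tibble, invisibly.
#' @export
run_predict <- function(paths, model_path, out) {
  model <- read_model(model_path)
  suites <- dplyr::bind_rows(lapply(paths, function(p) {
    tryCatch(build_suites(read_rna_atoms(p)), error = function(e) {
      warning(sprintf("skipping %s: %s", p, conditionMessage(e)), call. = FALSE)
      NULL
    })
  }))
  preds <- predict(model, suites)
  readr::write_csv(dplyr::select(preds, -"ranking"), out)
  invisible(preds)
}

#' Evaluate predictions on disk
#'
#' @param predictions_csv Predictions CSV from [run_predict()].
#' @param manifest_csv Answer manifest CSV.
#' @param model_path Model JSON.
#' @param out Output evaluation CSV; a summary table is printed.
#' @return The evaluation list, invisibly.
#' @export
run_evaluate <- function(predictions_csv, manifest_csv, model_path, out) {
  preds <- readr::read_csv(predictions_csv, show_col_types = FALSE)
  preds$icode[is.na(preds$icode)] <- ""
  manifest <- readr::read_csv(manifest_csv, show_col_types = FALSE)
  manifest$icode[is.na(manifest$icode)] <- ""
  model <- read_model(model_path)
  ev <- precis_evaluate(preds, manifest, model)
  readr::write_csv(ev$records, out)
  print(ev$summary)
  invisible(ev)
}
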