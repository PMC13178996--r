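#' Read RNA atoms from a coordinate file
#'
#' Parses a PDB or mmCIF coordinate file (via bio3d), keeps the first model
#' only, selects RNA residues, applies the alternate-location policy (altloc
#' "A" or blank; highest occupancy on ties) and returns a flat atom table.
#' Residues are kept when they contain at least one of the atoms the suite
#' machinery uses; base types are normalised to A, U, C, G (common aliases
#' accepted) and other residues dropped.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return Tibble with columns `structure_id`, `chain`, `resnum`, `icode`,
#'   `base`, `atom`, `x`, `y`, `z`, `altloc`, `occupancy`, `has_altloc`.
#' @export
read_rna_atoms <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    withCallingHandlers(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, verbose = FALSE),
      warning = function(w) {
        # read.cif always emits advisory warnings irrelevant to coordinates
        if (grepl("beta version|helix/sheet", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    error = function(e) stop(sprintf("cannot parse %s as %s: %s",
                                     path, format, conditionMessage(e)),
                             call. = FALSE)
  )
  at <- parsed$atom
  structure_id <- sub("\\.(pdb|cif|ent)$", "", basename(path), ignore.case = TRUE)
  tb <- tibble::tibble(
    structure_id = structure_id,
    chain = as.character(at$chain),
    resnum = as.integer(at$resno),
    icode = ifelse(is.na(at$insert) | at$insert == "", "", as.character(at$insert)),
    base = normalize_base(at$resid),
    atom = gsub('^"|"$', "", as.character(at$elety)),
    x = at$x, y = at$y, z = at$z,
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    occupancy = ifelse(is.na(at$o), 1, at$o)
  )
  tb <- tb[!is.na(tb$base), ]
  if (nrow(tb) == 0) {
    warning(sprintf("no RNA residues found in %s", path), call. = FALSE)
    return(tb[0, ])
  }
  # altloc policy: prefer blank or "A", then highest occupancy, per atom site
  tb <- tb |>
    dplyr::group_by(.data$chain, .data$resnum, .data$icode, .data$atom) |>
    dplyr::mutate(has_altloc = any(.data$altloc != "")) |>
    dplyr::arrange(ifelse(.data$altloc == "", 0L, ifelse(.data$altloc == "A", 1L, 2L)),
                   .data$altloc, dplyr::desc(.data$occupancy), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  # keep residues with at least one downstream atom
  used <- c("P", "O5'", "C5'", "C4'", "C3'", "O3'", "O4'", "C1'", "C2'", "N1", "N9")
  keep <- tb |>
    dplyr::group_by(.data$chain, .data$resnum, .data$icode) |>
    dplyr::filter(any(.data$atom %in% used)) |>
    dplyr::ungroup()
  if (nrow(keep) == 0) warning(sprintf("no usable RNA residues in %s", path), call. = FALSE)
  dplyr::arrange(keep, .data$chain, .data$resnum, .data$icode)
}

# base-name normalisation; returns NA for non-AUCG residues
normalize_base <- function(resid) {
  r <- toupper(trimws(as.character(resid)))
  map <- c(A = "A", ADE = "A", RA = "A", "A5" = "A", "A3" = "A",
           U = "U", URA = "U", URI = "U", RU = "U",
           C = "C", CYT = "C", RC = "C",
           G = "G", GUA = "G", RG = "G")
  out <- unname(map[r])
  out
}

#' Assemble suites from an atom table
#'
#' Builds one suite per pair of sequence-adjacent, covalently connectable
#' residues (O3' of the first within `bond_cutoff` of P of the second). The
#' suite is named by the residue number of its second member. The phosphorus
#' of the following residue is attached when that residue exists and is
#' bonded. Suites missing any of the five low-detail atoms (glycosidic N and
#' C1' on both sides, plus the central P) are dropped with a message, so
#' every returned suite supports the low-detail representation.
#'
#' @param atoms Atom tibble from [read_rna_atoms()].
#' @param bond_cutoff O3'-P bondedness cutoff in Angstrom.
#' @param drop_altloc Drop suites any of whose atoms had alternate locations.
#' @return Suite tibble: `structure_id`, `chain`, `resnum`, `icode`,
#'   `base_prev`, `base_curr`, and list-column `atoms` (matrices `prev`,
#'   `curr`, optional `next_P`).
#' @export
build_suites <- function(atoms, bond_cutoff = 2.5, drop_altloc = FALSE) {
  if (nrow(atoms) == 0) return(empty_suite_table())
  if (!"has_altloc" %in% names(atoms)) atoms$has_altloc <- FALSE
  res <- atoms |>
    dplyr::group_by(.data$structure_id, .data$chain, .data$resnum, .data$icode) |>
    dplyr::group_split()
  ord <- order(
    vapply(res, function(r) r$structure_id[1], ""),
    vapply(res, function(r) r$chain[1], ""),
    vapply(res, function(r) r$resnum[1], 0L),
    vapply(res, function(r) r$icode[1], "")
  )
  res <- res[ord]
  mat <- lapply(res, function(r) {
    m <- as.matrix(r[, c("x", "y", "z")])
    rownames(m) <- r$atom
    m
  })
  info <- lapply(res, function(r) list(
    structure_id = r$structure_id[1], chain = r$chain[1],
    resnum = r$resnum[1], icode = r$icode[1], base = r$base[1],
    any_alt = any(r$has_altloc)
  ))
  bonded <- function(i, j) {
    mi <- mat[[i]]; mj <- mat[[j]]
    same <- info[[i]]$structure_id == info[[j]]$structure_id &&
      info[[i]]$chain == info[[j]]$chain
    if (!same || !"O3'" %in% rownames(mi) || !"P" %in% rownames(mj)) return(FALSE)
    vnorm(mi["O3'", ] - mj["P", ]) <= bond_cutoff
  }
  out <- list()
  dropped <- 0L
  for (k in seq_along(res)[-1]) {
    if (!bonded(k - 1, k)) next
    prev <- mat[[k - 1]]; curr <- mat[[k]]
    ld_ok <- all(c("C1'") %in% rownames(prev)) &&
      any(c("N1", "N9") %in% rownames(prev)) &&
      all(c("P", "C1'") %in% rownames(curr)) &&
      any(c("N1", "N9") %in% rownames(curr))
    if (!ld_ok) { dropped <- dropped + 1L; next }
    if (drop_altloc && (info[[k - 1]]$any_alt || info[[k]]$any_alt)) {
      dropped <- dropped + 1L; next
    }
    nxt <- if (k + 1 <= length(res) && bonded(k, k + 1)) mat[[k + 1]]["P", ] else NULL
    out[[length(out) + 1]] <- tibble::tibble(
      structure_id = info[[k]]$structure_id, chain = info[[k]]$chain,
      resnum = info[[k]]$resnum, icode = info[[k]]$icode,
      base_prev = info[[k - 1]]$base, base_curr = info[[k]]$base,
      atoms = list(list(prev = prev, curr = curr, next_P = nxt))
    )
  }
  if (dropped > 0) {
    message(sprintf("build_suites: dropped %d suite(s) missing low-detail atoms or filtered by altloc policy", dropped))
  }
  if (!length(out)) return(empty_suite_table())
  dplyr::bind_rows(out)
}

empty_suite_table <- function() {
  tibble::tibble(structure_id = character(), chain = character(),
                 resnum = integer(), icode = character(),
                 base_prev = character(), base_curr = character(),
                 atoms = list())
}

#' Suite identifier strings
#'
#' @param suites A suite tibble.
#' @return Character vector "structure chain resnum[icode]".
#' @export
suite_ids <- function(suites) {
  paste0(suites$structure_id, " ", suites$chain, " ", suites$resnum,
         suites$icode)
}

# ---- label tables and manifests --------------------------------------------

conformer_ok <- function(x) grepl("^..$", x) | x == "!!"

#' Read a conformer label table
#'
#' Reads the delimited label format (header columns `structure_id`, `chain`,
#' `resnum`, `icode`, `conformer`, optionally `answer_conformer` and
#' `answer_pucker_pair`). Rows whose conformer string is not two characters
#' (or "!!") are rejected with a diagnostic message.
#'
#' @param path CSV file path.
#' @return Tibble of labels.
#' @export
read_label_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          resnum = readr::col_integer(),
                          icode = readr::col_character(),
                          .default = readr::col_character()
                        ))
  if (nrow(tb) == 0) return(tb)
  tb$icode[is.na(tb$icode)] <- ""
  label_col <- intersect(c("conformer", "answer_conformer"), names(tb))[1]
  bad <- !conformer_ok(tb[[label_col]])
  if (any(bad)) {
    message(sprintf("read_label_table: rejected %d row(s) with malformed conformer strings: %s",
                    sum(bad), paste(utils::head(tb[[label_col]][bad], 5), collapse = ", ")))
    tb <- tb[!bad, ]
  }
  tb
}

#' Write a conformer label table
#'
#' @param labels Tibble as produced by [read_label_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(path)
}

#' Write atoms as a minimal mmCIF file
#'
#' Emits an `atom_site` loop with the standard coordinate items. Intended for
#' fixtures and round-trip checks; not a general-purpose mmCIF writer.
#'
#' @param atoms Atom tibble (as from [read_rna_atoms()]).
#' @param path Output path.
#' @param entry_id Entry identifier.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(atoms, path, entry_id = "XXXX") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("data_%s", entry_id), con)
  # the canonical PDBx/mmCIF atom_site column layout, as deposited entries use
  writeLines(c(
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  ), con)
  elem <- substr(gsub("[^A-Za-z]", "", atoms$atom), 1, 1)
  altloc <- if (is.null(atoms$altloc)) rep("", nrow(atoms)) else atoms$altloc
  alt <- ifelse(altloc == "", ".", altloc)
  ic <- ifelse(atoms$icode == "", "?", atoms$icode)
  occ <- if (is.null(atoms$occupancy)) rep(1, nrow(atoms)) else atoms$occupancy
  atom_q <- sprintf('"%s"', atoms$atom)
  lines <- sprintf('ATOM %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1',
                   seq_len(nrow(atoms)), elem, atom_q, alt, atoms$base,
                   atoms$chain, atoms$resnum, ic,
                   atoms$x, atoms$y, atoms$z, occ, 0,
                   atoms$resnum, atoms$base, atoms$chain, atom_q)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}
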