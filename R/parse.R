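# Molecule input: SMILES (one record per line, optional whitespace-separated
# name) and SDF/MDL V2000. SMILES records are converted to kekulized V2000
# blocks by OpenBabel (via ChemmineOB); SDF records are split and parsed with
# ChemmineR. Unparseable records become placeholder molecules flagged for
# missing-value propagation; only an unreadable file is fatal.

#' Read molecules from SMILES or SDF input
#'
#' @param input path to a file, or raw text (multi-line character scalar or a
#'   character vector of lines). A string that names an existing file is read
#'   as a file.
#' @param format `"smiles"`, `"sdf"`, or `"auto"` (by file extension:
#'   `.sdf`/`.mol`/`.mdl` is SDF, anything else SMILES; raw text defaults to
#'   SMILES unless it contains an SDF counts line).
#' @return A list of [mol_graph()] objects, one per input record in input
#'   order. Records that fail to parse are placeholders for which
#'   [is_parse_failure()] is `TRUE`.
#' @examples
#' mols <- read_molecules("CCO ethanol", format = "smiles")
#' mols[[1]]
#' @export
read_molecules <- function(input, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  is_file <- length(input) == 1L && !grepl("\n", input) && file.exists(input) &&
    !dir.exists(input)
  if (!is_file && length(input) == 1L && grepl("[/\\\\]", input) &&
      !grepl("\n", input) && !grepl("[A-Za-z0-9]\\s", trimws(input))) {
    # looks like a path (has separators, no record structure) but is absent
    stop("input file not found: ", input)
  }
  if (is_file) {
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(as.character(input), "\n", fixed = TRUE))
  }
  if (format == "auto") {
    if (is_file && grepl("\\.(sdf|mol|mdl)$", tolower(input))) {
      format <- "sdf"
    } else if (!is_file && any(grepl("V2000", lines, fixed = TRUE))) {
      format <- "sdf"
    } else {
      format <- "smiles"
    }
  }
  if (format == "smiles") read_smiles_lines(lines) else read_sdf_lines(lines)
}

read_smiles_lines <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "\\s+")[[1]]
    smi <- parts[1]
    nm <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else paste0("mol", k)
    out[[k]] <- parse_one_smiles(smi, nm)
  }
  out
}

parse_one_smiles <- function(smiles, name = "") {
  sdf_txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))),
    error = function(e) ""
  )
  if (!nzchar(sdf_txt)) return(parse_failure_mol(name, paste("bad SMILES:", smiles)))
  rec <- unlist(strsplit(sdf_txt, "\n", fixed = TRUE))
  m <- tryCatch(parse_v2000_record(rec), error = function(e) NULL)
  if (is.null(m)) return(parse_failure_mol(name, paste("bad SMILES:", smiles)))
  m$name <- name
  m
}

read_sdf_lines <- function(lines) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  sdfstr <- ChemmineR::read.SDFstr(tf)
  recs <- methods::as(sdfstr, "list")
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    nm <- if (length(rec) >= 1L && nzchar(trimws(rec[1]))) trimws(rec[1]) else paste0("mol", k)
    m <- tryCatch(parse_v2000_record(rec), error = function(e) NULL)
    out[[k]] <- if (is.null(m)) parse_failure_mol(nm, "malformed SDF record") else m
  }
  out
}

# Parse one V2000 record given as a character vector of lines. ChemmineR
# handles record splitting; the connection table is read here so that formal
# charges ("M  CHG", which supersede old-style atom-line charge codes) and
# exact bond orders survive.
parse_v2000_record <- function(rec) {
  if (length(rec) < 4L) stop("record too short")
  counts <- rec[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1L) stop("bad counts line")
  if (length(rec) < 4L + na + nb) stop("truncated connection table")
  atom_lines <- rec[4L + seq_len(na)]
  bond_lines <- if (nb > 0L) rec[4L + na + seq_len(nb)] else character(0)

  elements <- trimws(substr(atom_lines, 32, 34))
  old_chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  old_chg_code[is.na(old_chg_code)] <- 0L
  # MDL old-style codes: 1:+3 2:+2 3:+1 5:-1 6:-2 7:-3 (4 = radical, ignored)
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  charges <- integer(na)
  hit <- old_chg_code %in% as.integer(names(code_map))
  charges[hit] <- code_map[as.character(old_chg_code[hit])]

  # "M  CHG" property lines override all old-style codes when present
  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines)) {
    charges <- integer(na)
    for (cl in chg_lines) {
      flds <- suppressWarnings(as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]]))
      cnt <- flds[1]
      for (t in seq_len(cnt)) {
        idx <- flds[2 * t]; val <- flds[2 * t + 1]
        if (!is.na(idx) && idx >= 1L && idx <= na) charges[idx] <- val
      }
    }
  }

  if (nb > 0L) {
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    bo <- as.integer(substr(bond_lines, 7, 9))
    if (anyNA(bi) || anyNA(bj) || anyNA(bo)) stop("bad bond block")
    bonds <- cbind(bi, bj, bo)
  } else {
    bonds <- NULL
  }
  nm <- trimws(rec[1])
  m <- mol_graph(elements, bonds, charges = charges, name = nm)
  # kekulized input: perceive aromatic flags once at the parser boundary
  perceive_aromaticity_(m)
}
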