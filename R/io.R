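#' Read a molecule collection from an SDF or SMILES file
#'
#' SDF records are parsed with ChemmineR (MDL V2000; V3000 records are
#' accepted when the underlying parser handles them); `M  CHG` and `M  ISO`
#' property lines are honoured. SMILES files contain one record per line,
#' with an optional whitespace-separated name. Unparsable records are
#' skipped and counted in the `skipped` attribute of the result; an input
#' with zero parsable records yields an empty list with a warning.
#'
#' @param path file path.
#' @param format `"sdf"` or `"smiles"`.
#' @return list of `mol_graph` objects (each carrying a `name` attribute
#'   when one was present), with attribute `skipped` = number of records
#'   that failed to parse.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("c1ccccc1 benzene", "CCO ethanol"), f)
#' mols <- read_molecules(f, "smiles")
#' length(mols)
#' @export
read_molecules <- function(path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "sdf") read_sdf_file(path) else read_smiles_file(path)
}

read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mols <- list()
  skipped <- 0L
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    smi <- parts[1]
    nm <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else NULL
    g <- tryCatch(parse_smiles(smi), error = function(e) NULL)
    if (is.null(g)) {
      skipped <- skipped + 1L
    } else {
      if (!is.null(nm)) attr(g, "name") <- nm
      mols[[length(mols) + 1L]] <- g
    }
  }
  if (!length(mols)) warning("no parsable records in ", path, call. = FALSE)
  attr(mols, "skipped") <- skipped
  mols
}

read_sdf_file <- function(path) {
  sds <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(path)))
  raw <- suppressWarnings(ChemmineR::read.SDFstr(path))
  reclines <- as(raw, "list")
  ok <- tryCatch(ChemmineR::validSDF(sds), error = function(e)
    rep(FALSE, length(sds)))
  mols <- list()
  skipped <- sum(!ok)
  for (i in which(ok)) {
    ml <- if (i <= length(reclines)) reclines[[i]] else character()
    g <- tryCatch(graph_from_sdf(sds[[i]], ml), error = function(e) NULL)
    if (is.null(g)) {
      skipped <- skipped + 1L
      next
    }
    mols[[length(mols) + 1L]] <- g
  }
  if (!length(mols)) warning("no parsable records in ", path, call. = FALSE)
  attr(mols, "skipped") <- skipped
  mols
}

#' Write molecules to an SD file
#'
#' Serialises each graph through its SMILES form into an MDL V2000 record
#' (via Open Babel). Molecule `name` attributes become record titles.
#'
#' @param mols list of `mol_graph` objects (or a single one).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  recs <- vapply(mols, function(m) {
    smi <- write_smiles_raw(as_mol_graph(m), include_stereo = TRUE,
                            include_isotopes = TRUE)
    nm <- attr(m, "name")
    line <- paste0(smi, if (!is.null(nm)) paste0(" ", nm), "\n")
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", line))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sub("\n$", "", recs), con)
  invisible(path)
}

#' Parse SMILES strings into molecular graphs
#'
#' Uses Open Babel to interpret the SMILES (aromatic forms are kekulised)
#' and returns the heavy-atom graph with implicit hydrogen counts and
#' tetrahedral stereo descriptors. Aromatic flags are not set by parsing;
#' they are assigned by [perceive_aromaticity()].
#'
#' @param smiles character vector of SMILES strings.
#' @return a single `mol_graph` if one string was given, else a list.
#' @examples
#' parse_smiles("O=C1CCCCC1")
#' @export
parse_smiles <- function(smiles) {
  out <- lapply(smiles, parse_smiles_one)
  if (length(smiles) == 1L) out[[1]] else out
}

parse_smiles_one <- function(smi) {
  sdf <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF",
                                                    paste0(smi, "\n")))
  if (!nzchar(trimws(gsub("\\$\\$\\$\\$", "", sdf)))) {
    stop("invalid SMILES: ", smi, call. = FALSE)
  }
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sds <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(tf)))
  graph_from_sdf(sds[[1]], lines)
}

# old ctab charge column codes
.ctab_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

# Build a mol_graph from a ChemmineR SDF object plus the raw record lines
# (needed for M CHG / M ISO, which ChemmineR's blocks do not carry).
graph_from_sdf <- function(sdf, rawlines = character()) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  bonds <- if (length(bb) && nrow(bb)) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]), aromatic = FALSE)
  } else empty_bond_table()

  # aromatic (order 4) ctab bonds: re-kekulise the record through Open Babel
  if (nrow(bonds) && any(!(bonds$order %in% 1:3))) {
    rec <- paste0(paste(rawlines, collapse = "\n"), "\n$$$$\n")
    smi <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", rec))
    smi <- sub("[ \t].*$", "", strsplit(smi, "\n")[[1]][1])
    if (!nzchar(smi)) stop("cannot kekulise aromatic ctab record",
                           call. = FALSE)
    g <- parse_smiles_one(smi)
    attr(g, "name") <- sdf_record_name(sdf)
    return(g)
  }

  charge_code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else
    integer(n)
  charges <- unname(.ctab_charge[as.character(pmax(pmin(charge_code, 7L), 0L))])
  charges[is.na(charges)] <- 0L
  parity <- if ("C7" %in% colnames(ab)) as.integer(ab[, "C7"]) else integer(n)

  # property block overrides
  mchg <- parse_m_line(rawlines, "M  CHG")
  if (length(mchg)) {
    charges <- integer(n)
    for (p in mchg) charges[p[1]] <- p[2]
  }
  isotopes <- rep(NA_integer_, n)
  miso <- parse_m_line(rawlines, "M  ISO")
  for (p in miso) isotopes[p[1]] <- p[2]

  atoms <- data.frame(element = elements, charge = as.integer(charges),
                      nh = 0L, aromatic = FALSE, isotope = isotopes,
                      stringsAsFactors = FALSE)
  m <- mol_graph(atoms, bonds)
  m <- recompute_hydrogens(m)
  m <- fold_explicit_hydrogens(m)
  m <- add_ctab_stereo(m, parity)
  attr(m, "name") <- sdf_record_name(sdf)
  m
}

sdf_record_name <- function(sdf) {
  nm <- tryCatch(unname(ChemmineR::header(sdf)[["Molecule_Name"]]),
                 error = function(e) "")
  if (is.null(nm) || is.na(nm)) nm <- ""
  trimws(nm)
}

# "M  CHG  2   1   1   3  -1" -> list(c(atom, value), ...)
parse_m_line <- function(lines, tag) {
  out <- list()
  for (ln in grep(paste0("^", tag), lines, value = TRUE)) {
    vals <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)),
                                                 "[ \t]+")[[1]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 3L) next
    cnt <- vals[1]
    for (k in seq_len(cnt)) {
      a <- vals[2L * k]
      v <- vals[2L * k + 1L]
      if (!is.na(a) && !is.na(v)) out[[length(out) + 1L]] <- c(a, v)
    }
  }
  out
}

# collapse explicit plain hydrogens (single, uncharged, unlabelled) into
# implicit counts on their heavy neighbor
fold_explicit_hydrogens <- function(m) {
  repeat {
    deg <- mol_degree(m)
    h <- which(m$atoms$element == "H" & m$atoms$charge == 0L &
                 is.na(m$atoms$isotope) & deg == 1L)
    if (!length(h)) break
    # the heavy neighbor gains one hydrogen via delete_atoms' bookkeeping,
    # but only for single bonds
    hb <- vapply(h, function(a) {
      bi <- which(m$bonds$a1 == a | m$bonds$a2 == a)
      if (length(bi) == 1L && m$bonds$order[bi] == 1L) a else NA_integer_
    }, integer(1))
    hb <- hb[!is.na(hb)]
    if (!length(hb)) break
    m <- delete_atoms(m, hb)
  }
  m
}

# convert ctab parity codes into stereo_center descriptors
add_ctab_stereo <- function(m, parity) {
  if (!length(parity) || all(parity == 0L)) return(m)
  # parity vector refers to pre-fold indices only when no explicit H were
  # folded; Open Babel writes heavy-atom ctabs for SMILES input, so indices
  # line up in the supported paths.
  if (length(parity) != nrow(m$atoms)) return(m)
  inc <- incident_bonds(m)
  stereo <- m$stereo
  for (a in which(parity %in% c(1L, 2L))) {
    nb <- sort(vapply(inc[[a]], function(bi) {
      if (m$bonds$a1[bi] == a) m$bonds$a2[bi] else m$bonds$a1[bi]
    }, integer(1)))
    if (length(nb) == 3L && m$atoms$nh[a] == 1L) {
      nb <- c(nb, 0L)                      # implicit H is highest-numbered
    }
    if (length(nb) != 4L) next
    stereo[[length(stereo) + 1L]] <- stereo_center(a, nb, parity[a])
  }
  m$stereo <- stereo
  m
}
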