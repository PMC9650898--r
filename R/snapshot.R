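#' Performance snapshot over an SD file
#'
#' Reproduces the snapshot protocol of the command-line application: import
#' all molecules from an SD file, discard structures with more than ten
#' rings (they are rare but would dominate the processing time
#' disproportionally), run the Schuffenhauer and the enumerative dissection
#' over every remaining molecule, then build a scaffold forest and a
#' scaffold network over growing unions of `n_fractions` equally sized
#' subsets, logging molecule counts and elapsed times at every step.
#' Finally all scaffolds of the network and of the forest are exported as
#' SMILES strings with their frequencies. Timing lines go to `stderr`;
#' exports are files under `out_dir`.
#'
#' @param sdf_path input SD file.
#' @param n_fractions number of equally sized subsets (>= 1, at most the
#'   number of retained molecules).
#' @param out_dir output directory (created if missing).
#' @param settings a [scaffold_settings()].
#' @return A `snapshot_report`: list with `input_count`, `filtered_count`,
#'   `timings` (data.frame: structure, n_molecules, elapsed_ms) and
#'   `export_paths`.
#' @export
run_snapshot <- function(sdf_path, n_fractions, out_dir,
                         settings = scaffold_settings()) {
  mols <- read_molecules(sdf_path, "sdf")
  if (!length(mols)) stop("no molecules imported from ", sdf_path,
                          call. = FALSE)
  input_count <- length(mols) + attr(mols, "skipped")
  ring_counts <- vapply(mols, function(m)
    length(detect_rings_graph(as_mol_graph(m))$rings), integer(1))
  keep <- ring_counts <= 10L
  filtered_count <- sum(!keep)
  mols <- mols[keep]
  if (!length(mols)) stop("all molecules filtered (> 10 rings)",
                          call. = FALSE)
  if (n_fractions < 1L || n_fractions > length(mols)) {
    stop("n_fractions must be between 1 and the number of retained ",
         "molecules (", length(mols), ")", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  log_line <- function(phase, n, ms) {
    message(sprintf("[snapshot] phase=%s n_molecules=%d elapsed_ms=%.0f",
                    phase, n, ms))
  }
  timings <- list()
  clock <- function(phase, n, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    ms <- (proc.time()[["elapsed"]] - t0) * 1000
    log_line(phase, n, ms)
    timings[[length(timings) + 1L]] <<-
      data.frame(structure = phase, n_molecules = n, elapsed_ms = ms)
    val
  }

  clock("schuffenhauer_dissection", length(mols),
        lapply(mols, schuffenhauer_chain, settings = settings))
  clock("enumerative_dissection", length(mols),
        lapply(mols, enumerate_parent_scaffolds, settings = settings))

  splits <- split(seq_along(mols),
                  ceiling(seq_along(mols) / (length(mols) / n_fractions)))
  forest <- NULL
  network <- NULL
  for (k in seq_along(splits)) {
    idx <- sort(unlist(splits[seq_len(k)]))
    forest <- clock("forest", length(idx),
                    build_forest(mols[idx], settings))
    network <- clock("network", length(idx),
                     build_network(mols[idx], settings))
  }

  paths <- c(
    network = file.path(out_dir, "network_frequencies.tsv"),
    forest = file.path(out_dir, "forest_frequencies.tsv")
  )
  export_frequencies(network, paths[["network"]])
  export_frequencies(forest, paths[["forest"]])

  structure(list(input_count = input_count,
                 filtered_count = filtered_count,
                 timings = do.call(rbind, timings),
                 export_paths = paths,
                 forest = forest, network = network),
            class = "snapshot_report")
}

#' @export
print.snapshot_report <- function(x, ...) {
  cat(sprintf("<snapshot_report> %d imported, %d filtered (> 10 rings)\n",
              x$input_count, x$filtered_count))
  print(x$timings, row.names = FALSE)
  invisible(x)
}

#' Dissect a single SMILES on the console
#'
#' Prints the scaffolds of the enumerative closure or the Schuffenhauer
#' chain of the given molecule, one SMILES per line, original scaffold
#' first (the empty scaffold prints as an empty line).
#'
#' @param smiles a SMILES string.
#' @param mode `"enumerative"` or `"schuffenhauer"`.
#' @param settings a [scaffold_settings()].
#' @return character vector of the printed SMILES keys, invisibly.
#' @export
dissect_command <- function(smiles, mode = c("enumerative",
                                             "schuffenhauer"),
                            settings = scaffold_settings()) {
  mode <- match.arg(mode)
  mol <- parse_smiles(smiles)
  res <- if (mode == "enumerative") {
    enumerate_parent_scaffolds(mol, settings)
  } else {
    schuffenhauer_chain(mol, settings)
  }
  keys <- vapply(res$scaffolds, function(s) s$smiles_key, character(1))
  cat(paste(keys, collapse = "\n"), "\n", sep = "")
  invisible(keys)
}
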