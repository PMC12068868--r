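#' Parse PSMC output text
#'
#' Reads the plain-text output of the `psmc` program: one block per EM
#' iteration, blocks separated by `//` lines. Each block carries an `RD`
#' line (round index), a `TR` line with the scaled mutation and
#' recombination rates per bin (theta0, rho0), an optional `PA` line with
#' the atomic time-interval pattern, and `RS` lines whose 2nd and 3rd
#' whitespace-separated fields are the coalescent-scaled segment start time
#' t_k and the relative size lambda_k. `RS` lines may carry further columns
#' (they do in real files); only columns 2 and 3 are consumed. Unknown line
#' codes (`LL`, `QD`, `RI`, `MM`, `MT`, `DC`, `TC`, ...) are skipped.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines in PSMC output format.
#' @param source_label Free-text identifier (taxon or replicate id) carried
#'   through to downstream tables.
#' @return An object of class `psmc_raw`: a list with elements `rounds`
#'   (list of `psmc_round`) and `source_label`. Each `psmc_round` has
#'   `round_index`, `theta0`, `rho0`, `max_t_coal`, `pattern`, and a
#'   two-column matrix `segments` with columns `t_k`, `lambda_k` in file
#'   order.
#' @seealso [read_psmc()], [last_round()], [scale_round()]
#' @export
parse_psmc <- function(text, source_label = "sample") {
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  rounds <- list()
  cur <- NULL
  new_round <- function() {
    list(round_index = NA_integer_, theta0 = NA_real_, rho0 = NA_real_,
         max_t_coal = NA_real_, pattern = NA_character_,
         t_k = numeric(0), lambda_k = numeric(0), rs_lines = integer(0))
  }
  num_or_stop <- function(x, lineno, code) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v)) || any(!nzchar(x))) {
      stop(sprintf("malformed %s numeric field at line %d: '%s'",
                   code, lineno, lines[lineno]), call. = FALSE)
    }
    v
  }
  close_round <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (length(cur$t_k) < 2L) {
      stop(sprintf("PSMC round %s has fewer than 2 RS segments",
                   cur$round_index), call. = FALSE)
    }
    seg <- cbind(t_k = cur$t_k, lambda_k = cur$lambda_k)
    structure(list(round_index = cur$round_index, theta0 = cur$theta0,
                   rho0 = cur$rho0, max_t_coal = cur$max_t_coal,
                   pattern = cur$pattern, segments = seg),
              class = "psmc_round")
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, "//")) {
      r <- close_round(cur)
      if (!is.null(r)) rounds[[length(rounds) + 1L]] <- r
      cur <- NULL
      next
    }
    fields <- strsplit(trimws(ln), "[ \t]+")[[1]]
    code <- fields[1]
    if (code == "RD") {
      if (!is.null(cur)) {  # block not closed by "//"; tolerate
        r <- close_round(cur)
        if (!is.null(r)) rounds[[length(rounds) + 1L]] <- r
      }
      cur <- new_round()
      cur$round_index <- as.integer(num_or_stop(fields[2], i, "RD"))
    } else if (is.null(cur)) {
      next  # preamble outside any block
    } else if (code == "TR") {
      v <- num_or_stop(fields[2:3], i, "TR")
      cur$theta0 <- v[1]; cur$rho0 <- v[2]
    } else if (code == "MT") {
      cur$max_t_coal <- num_or_stop(fields[2], i, "MT")
    } else if (code == "PA") {
      cur$pattern <- paste(fields[-1], collapse = " ")
    } else if (code == "RS") {
      # row layout: RS <k> <t_k> <lambda_k> [...]; only t_k and lambda_k
      # (columns 2 and 3 after the code) are consumed
      if (length(fields) < 4L) {
        stop(sprintf("RS line %d has fewer than 3 columns", i), call. = FALSE)
      }
      v <- num_or_stop(fields[3:4], i, "RS")
      cur$t_k <- c(cur$t_k, v[1])
      cur$lambda_k <- c(cur$lambda_k, v[2])
    }
    # all other codes skipped
  }
  r <- close_round(cur)
  if (!is.null(r)) rounds[[length(rounds) + 1L]] <- r
  if (length(rounds) == 0L) {
    stop("no PSMC blocks found in input (empty input?)", call. = FALSE)
  }
  for (r in rounds) {
    tk <- r$segments[, "t_k"]
    if (tk[1] != 0 || any(diff(tk) <= 0)) {
      stop(sprintf("round %d: t_k must start at 0 and be strictly increasing",
                   r$round_index), call. = FALSE)
    }
    if (any(r$segments[, "lambda_k"] <= 0)) {
      stop(sprintf("round %d: all lambda_k must be > 0", r$round_index),
           call. = FALSE)
    }
    if (is.na(r$theta0) || r$theta0 <= 0) {
      stop(sprintf("round %d: missing or non-positive theta0 (TR line)",
                   r$round_index), call. = FALSE)
    }
  }
  structure(list(rounds = rounds, source_label = source_label),
            class = "psmc_raw")
}

#' Read a PSMC output file
#'
#' @param path Path to a `psmc` output file.
#' @param source_label Identifier; defaults to the file name without
#'   extension.
#' @return A `psmc_raw` object; see [parse_psmc()].
#' @export
read_psmc <- function(path, source_label = NULL) {
  if (is.null(source_label)) {
    source_label <- sub("\\.[^.]*$", "", basename(path))
  }
  parse_psmc(readLines(path, warn = FALSE), source_label = source_label)
}

#' Extract the converged (last) EM round
#'
#' `psmc` writes one block per EM iteration; the block with the highest
#' round index is the converged estimate and is what the standard plotting
#' utilities use.
#'
#' @param p A `psmc_raw` object.
#' @param round_index Optional explicit round index to select instead.
#' @return A `psmc_round`.
#' @export
last_round <- function(p, round_index = NULL) {
  stopifnot(inherits(p, "psmc_raw"), length(p$rounds) >= 1L)
  idx <- vapply(p$rounds, function(r) r$round_index, integer(1))
  if (!is.null(round_index)) {
    hit <- which(idx == round_index)
    if (length(hit) != 1L) {
      stop(sprintf("round index %d not found (available: %s)", round_index,
                   paste(idx, collapse = ", ")), call. = FALSE)
    }
    return(p$rounds[[hit]])
  }
  p$rounds[[which.max(idx)]]
}

#' @export
print.psmc_raw <- function(x, ...) {
  lr <- last_round(x)
  cat(sprintf("PSMC output '%s': %d EM round(s), last round %d with %d segments, theta0 = %g\n",
              x$source_label, length(x$rounds), lr$round_index,
              nrow(lr$segments), lr$theta0))
  invisible(x)
}

#' Read a Newick tree as an ape phylo object
#'
#' Thin wrapper around [ape::read.tree()] that enforces unique tip labels
#' and a minimum size, as required by the downstream topological
#' phylogenetic-signal test.
#'
#' @param text Newick string (used if `path` is NULL).
#' @param path Optional path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  tr <- if (!is.null(path)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    stop(sprintf("duplicate tip labels in tree: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  tr
}

.valid_groups <- c("migrant", "resident")

#' Read a lineage manifest
#'
#' The manifest is a TSV with header columns `taxon_id`, `group`,
#' `psmc_path` and an optional `replicates` column holding a
#' comma-separated list of bootstrap-replicate PSMC files. Groups must be
#' `migrant` or `resident`.
#'
#' @param path Path to the manifest TSV.
#' @param base_dir Directory against which relative `psmc_path` entries are
#'   resolved; defaults to the manifest's directory.
#' @return A data.frame with columns `taxon_id`, `group`, `psmc_path`,
#'   `replicate_paths` (list column).
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon_id", "group", "psmc_path")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop(sprintf("manifest is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(m$taxon_id)) {
    stop("manifest taxon_id values must be unique", call. = FALSE)
  }
  bad <- setdiff(unique(m$group), .valid_groups)
  if (length(bad)) {
    stop(sprintf("unknown group label(s) %s; allowed: %s",
                 paste(bad, collapse = ", "),
                 paste(.valid_groups, collapse = ", ")), call. = FALSE)
  }
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base_dir, p))
  m$psmc_path <- resolve(m$psmc_path)
  if ("replicates" %in% names(m)) {
    m$replicate_paths <- lapply(m$replicates, function(s) {
      if (is.na(s) || !nzchar(s)) character(0)
      else resolve(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
    })
    m$replicates <- NULL
  } else {
    m$replicate_paths <- replicate(nrow(m), character(0), simplify = FALSE)
  }
  m
}

#' Write a results table as locale-safe TSV
#'
#' Tab-delimited, "." decimal separator, one header row, UTF-8, no quoting
#' and no row names — the layout every stage of the pipeline reads back.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-lineage growth-statistics table
#'
#' Expects the Table-1-style layout written by [run_full()] /
#' [write_table()]: columns `taxon_id`, `group`, `mean_ne_e4`, `sd_ne_e4`,
#' `cv`, `degree`, `rate_per_yr`, `deltat_yr`.
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_growth_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("taxon_id", "group", "mean_ne_e4", "sd_ne_e4", "cv", "degree",
            "rate_per_yr", "deltat_yr")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(sprintf("growth table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- setdiff(unique(d$group), .valid_groups)
  if (length(bad)) {
    stop(sprintf("unknown group label(s) %s; allowed: %s",
                 paste(bad, collapse = ", "),
                 paste(.valid_groups, collapse = ", ")), call. = FALSE)
  }
  d
}

#' Packaged per-lineage growth statistics for 14 thrush lineages
#'
#' Published PSMC-derived growth statistics for 14 closely related thrush
#' lineages (genus *Catharus* plus *Hylocichla mustelina*): 8 long-distance
#' seasonal migrants and 6 Neotropical residents. Ne columns are in units
#' of 10^4 individuals, `deltat_yr` in years. This table is the canonical
#' worked example for the group-contrast stage.
#'
#' @return A data.frame in the layout of [read_growth_table()].
#' @export
thrush_growth_table <- function() {
  read_growth_table(system.file("extdata", "thrush_growth_stats.tsv",
                                package = "psmcgrowth", mustWork = TRUE))
}
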