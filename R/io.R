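# Catalog/query/match serialization and the command-line interface.
# CSV dialect: comma-separated, UTF-8, header row, '.' decimal separator.
# Catalog masses are printed to 10 decimals so that write -> read -> write
# is byte-identical; match output prints m/z to 4 decimals and ppm errors
# to 1 decimal. Logging goes to stderr so results stay pipe-safe.

.CATALOG_COLS <- c("name", "aliases", "terminal", "n", "disulfides",
                   "metal1", "metal2", "bridge", "formula",
                   "monoisotopic_mass")

#' Write a species catalog to CSV
#'
#' Deterministic, fully formatted output: rewriting an unchanged catalog
#' produces byte-identical files. Masses are printed to 10 decimal
#' places.
#'
#' @param catalog A `pyc_catalog` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_catalog()]
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(is.data.frame(catalog), all(.CATALOG_COLS %in% names(catalog)))
  df <- catalog[, .CATALOG_COLS, drop = FALSE]
  df$monoisotopic_mass <- sprintf("%.10f", df$monoisotopic_mass)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(.CATALOG_COLS, collapse = ","), con)
  if (nrow(df)) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = ","))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a species catalog from CSV
#'
#' @param path A CSV written by [write_catalog()].
#' @return A `pyc_catalog` data frame.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(name = "character",
                                       aliases = "character",
                                       terminal = "character",
                                       n = "integer",
                                       disulfides = "integer",
                                       metal1 = "character",
                                       metal2 = "character",
                                       bridge = "character",
                                       formula = "character",
                                       monoisotopic_mass = "numeric"))
  stopifnot(identical(names(df), .CATALOG_COLS))
  df[is.na(df)] <- ""  # empty metal columns read back as NA
  df$n <- as.integer(df$n); df$disulfides <- as.integer(df$disulfides)
  class(df) <- c("pyc_catalog", "data.frame")
  df
}

#' Read experimental query masses
#'
#' Accepts the two common shapes of an LC-MS mass list: a `.txt` file
#' with one m/z value per line (blank lines skipped), or a `.csv` with a
#' column named `mz` (or a single unnamed column).
#'
#' @param path Input file path.
#' @return Numeric vector of positive m/z values, in file order.
#' @export
read_query_masses <- function(path) {
  if (!file.exists(path)) stop(sprintf("query file not found: %s", path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) stop(sprintf("query file is empty: %s", path))
    col <- if ("mz" %in% names(df)) df[["mz"]]
           else if (ncol(df) == 1L) df[[1]]
           else stop("csv query file must have a column named 'mz' or a single column")
    vals <- suppressWarnings(as.numeric(col))
    if (anyNA(vals)) {
      stop(sprintf("non-numeric query value '%s' at line %d of %s",
                   col[which(is.na(vals))[1]], which(is.na(vals))[1] + 1L, path))
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) stop(sprintf("query file is empty: %s", path))
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop(sprintf("non-numeric query value '%s' at line %d of %s",
                   trimws(lines[keep])[bad], keep[bad], path))
    }
  }
  if (any(vals <= 0)) stop("query masses must be positive")
  vals
}

#' Write an annotation match table to CSV
#'
#' m/z values are printed to 4 decimals and ppm errors to 1 decimal.
#'
#' @param matches Output of [annotate_masses()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  cols <- c("query_mz", "name", "formula", "adduct", "theoretical_mz",
            "ppm_error", "terminal", "n", "disulfides", "metals", "bridge")
  stopifnot(is.data.frame(matches), all(cols %in% names(matches)))
  df <- matches[, cols, drop = FALSE]
  df$query_mz <- sprintf("%.4f", df$query_mz)
  df$theoretical_mz <- sprintf("%.4f", df$theoretical_mz)
  df$ppm_error <- sprintf("%.1f", df$ppm_error)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  if (nrow(df)) writeLines(do.call(paste, c(unname(as.list(df)), sep = ",")), con)
  invisible(path)
}

.log_msg <- function(...) message(sprintf(...))

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{build}{Enumerate a catalog and write it as CSV
#'     (\code{-o/--output}; enumeration restricted by \code{--terminals},
#'     \code{--metals}, \code{--n-min}, \code{--n-max},
#'     \code{--max-metals}, \code{--no-bridges}).}
#'   \item{annotate}{Match a query mass list (\code{-i/--input}, .txt or
#'     .csv) against the catalog with \code{--adducts}, \code{--ppm},
#'     \code{--nops}, and the same species filters; match table to
#'     \code{-o/--output} or stdout.}
#'   \item{fixtures}{Write a seeded synthetic query set
#'     (\code{--n-true}, \code{--n-decoys}, \code{--jitter-ppm},
#'     \code{--seed}) in query .txt format.}
#' }
#' Comma-separated values are accepted for list-valued flags. Logs go to
#' stderr; results to the output file (or stdout for annotate).
#'
#' A ready-to-run wrapper script is installed at
#' \code{system.file("scripts", "pyctools", package = "pyctools")}.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name), e.g. \code{c("build", "-o", "catalog.csv")}.
#' @return Integer exit status, invisibly (0 on success).
#' @export
pyc_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: pyctools <build|annotate|fixtures> [options]",
    "  build     -o FILE [--terminals L] [--metals L] [--n-min I] [--n-max I]",
    "            [--max-metals I] [--no-bridges]",
    "  annotate  -i FILE [-o FILE] [--adducts L] [--ppm X] [--nops]",
    "            [--terminals L] [--metals L] [--n-min I] [--n-max I]",
    "  fixtures  -o FILE [--n-true I] [--n-decoys I] [--jitter-ppm X] [--seed I]",
    sep = "\n")
  if (!length(argv) || argv[1] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(argv)) 0L else 1L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  status <- tryCatch({
    switch(cmd,
      build = .cli_build(rest),
      annotate = .cli_annotate(rest),
      fixtures = .cli_fixtures(rest),
      {
        message(sprintf("unknown subcommand '%s'\n%s", cmd, usage))
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(usage)
    1L
  })
  invisible(as.integer(status))
}

.split_list <- function(x) if (is.null(x)) NULL else strsplit(x, ",", fixed = TRUE)[[1]]

.cli_config_opts <- function() {
  list(
    optparse::make_option("--terminals", type = "character", default = NULL,
                          help = "comma-separated terminal residues"),
    optparse::make_option("--metals", type = "character", default = NULL,
                          help = "comma-separated metal symbols"),
    optparse::make_option("--n-min", type = "integer", default = 2L,
                          dest = "n_min"),
    optparse::make_option("--n-max", type = "integer", default = 11L,
                          dest = "n_max")
  )
}

.cli_build <- function(args) {
  opts <- c(list(
    optparse::make_option(c("-o", "--output"), type = "character",
                          default = NULL, help = "catalog CSV path"),
    optparse::make_option("--max-metals", type = "integer", default = 2L,
                          dest = "max_metals"),
    optparse::make_option("--no-bridges", action = "store_true",
                          default = FALSE, dest = "no_bridges")),
    .cli_config_opts())
  p <- optparse::OptionParser(option_list = opts, add_help_option = FALSE)
  o <- optparse::parse_args(p, args = args)
  if (is.null(o$output)) stop("build requires -o/--output")
  cfg <- enumeration_config(
    terminals = .split_list(o$terminals) %||% .TERMINALS,
    n_min = o$n_min, n_max = o$n_max,
    metals = .split_list(o$metals) %||% .METALS,
    max_metals = o$max_metals, include_bridges = !o$no_bridges)
  t0 <- proc.time()[["elapsed"]]
  catalog <- enumerate_catalog(cfg)
  write_catalog(catalog, o$output)
  .log_msg("build: %d species written to %s (%.2f s)",
           nrow(catalog), o$output, proc.time()[["elapsed"]] - t0)
  0L
}

.cli_annotate <- function(args) {
  opts <- c(list(
    optparse::make_option(c("-i", "--input"), type = "character",
                          default = NULL, help = "query mass list (.txt/.csv)"),
    optparse::make_option(c("-o", "--output"), type = "character",
                          default = NULL, help = "match CSV (default stdout)"),
    optparse::make_option("--catalog", type = "character", default = NULL,
                          help = "catalog CSV (default: enumerate with filters)"),
    optparse::make_option("--adducts", type = "character", default = "M+H"),
    optparse::make_option("--ppm", type = "double", default = 5),
    optparse::make_option("--nops", action = "store_true", default = FALSE),
    optparse::make_option("--no-nops", action = "store_false", dest = "nops")),
    .cli_config_opts())
  p <- optparse::OptionParser(option_list = opts, add_help_option = FALSE)
  o <- optparse::parse_args(p, args = args)
  if (is.null(o$input)) stop("annotate requires -i/--input")
  t0 <- proc.time()[["elapsed"]]
  queries <- read_query_masses(o$input)
  catalog <- if (!is.null(o$catalog)) read_catalog(o$catalog)
             else enumerate_catalog(enumeration_config(
               terminals = .split_list(o$terminals) %||% .TERMINALS,
               metals = .split_list(o$metals) %||% .METALS,
               n_min = o$n_min, n_max = o$n_max))
  .log_msg("annotate: %d queries vs %d species, adducts %s, +/- %g ppm, nops %s",
           length(queries), nrow(catalog), o$adducts, o$ppm, o$nops)
  matches <- annotate_masses(
    queries, catalog, adducts = .split_list(o$adducts),
    tolerance_ppm = o$ppm,
    metals = .split_list(o$metals), terminals = .split_list(o$terminals),
    n_range = c(o$n_min, o$n_max), nops = o$nops)
  out <- o$output %||% ""
  if (nzchar(out)) write_matches(matches, out)
  else {
    tmp <- tempfile(fileext = ".csv")
    write_matches(matches, tmp)
    writeLines(readLines(tmp))
    unlink(tmp)
  }
  .log_msg("annotate: %d matches for %d of %d queries (%.2f s)",
           nrow(matches), length(unique(matches$query_mz)), length(queries),
           proc.time()[["elapsed"]] - t0)
  0L
}

.cli_fixtures <- function(args) {
  opts <- c(list(
    optparse::make_option(c("-o", "--output"), type = "character",
                          default = NULL, help = "query .txt path"),
    optparse::make_option("--n-true", type = "integer", default = 100L,
                          dest = "n_true"),
    optparse::make_option("--n-decoys", type = "integer", default = 20L,
                          dest = "n_decoys"),
    optparse::make_option("--jitter-ppm", type = "double", default = 1,
                          dest = "jitter_ppm"),
    optparse::make_option("--seed", type = "integer", default = 1L)),
    .cli_config_opts())
  p <- optparse::OptionParser(option_list = opts, add_help_option = FALSE)
  o <- optparse::parse_args(p, args = args)
  if (is.null(o$output)) stop("fixtures requires -o/--output")
  catalog <- enumerate_catalog(enumeration_config(
    terminals = .split_list(o$terminals) %||% .TERMINALS,
    metals = .split_list(o$metals) %||% .METALS,
    n_min = o$n_min, n_max = o$n_max))
  qs <- generate_query_set(catalog, n_true = o$n_true, n_decoys = o$n_decoys,
                           jitter_ppm_sd = o$jitter_ppm, seed = o$seed)
  writeLines(sprintf("%.6f", qs$queries), o$output)
  .log_msg("fixtures: %d queries (%d true, %d decoys) written to %s",
           length(qs$queries), o$n_true, o$n_decoys, o$output)
  0L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
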