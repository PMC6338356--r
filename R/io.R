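## Readers/writers for the S1-style count table, chain outputs and the
## command-line interface.
##
## Native table dialect (whitespace- or tab-delimited, optional header):
##   M N Sf Snp Slp Rf Rnp Rlp Locus Class
## mapped internally to m, n, Ks, Os, Hs, Kr, Or, Hr, locus, class.

.s1_cols <- c("M", "N", "Sf", "Snp", "Slp", "Rf", "Rnp", "Rlp",
              "Locus", "Class")
.class_map <- c(M = "male-biased", F = "female-biased", U = "sex-unbiased")

#' Read a polymorphism/divergence counts table
#'
#' Accepts both headered and headerless files; when a header is present it
#' must contain the columns `M N Sf Snp Slp Rf Rnp Rlp Locus Class` (any
#' order), otherwise strict column order is assumed. Class codes `M/F/U` are
#' mapped to `male-biased/female-biased/sex-unbiased`; other values pass
#' through (unrecognized ones become `"unknown"`).
#'
#' @param path file path.
#' @return validated data frame with columns `m, n, Ks, Os, Hs, Kr, Or, Hr,
#'   locus, class` and attribute `source` (the path).
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("no data rows in ", path)
  toks <- strsplit(trimws(first), "[ \t]+")[[1]]
  has_header <- any(tolower(toks) %in% tolower(.s1_cols)) &&
    all(is.na(suppressWarnings(as.numeric(toks[1:2]))))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (has_header) {
    miss <- setdiff(tolower(.s1_cols), tolower(names(df)))
    if (length(miss))
      stop("missing required column(s): ", paste(miss, collapse = ", "))
    df <- df[, match(tolower(.s1_cols), tolower(names(df)))]
  } else {
    if (ncol(df) != 10L)
      stop("headerless table must have exactly 10 columns (got ", ncol(df), ")")
  }
  names(df) <- c("m", "n", "Ks", "Os", "Hs", "Kr", "Or", "Hr",
                 "locus", "class")
  num <- c("m", "n", "Ks", "Os", "Hs", "Kr", "Or", "Hr")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("malformed value in column %s, row %d: %s",
                   cn, bad[1], df[[cn]][bad[1]]))
    df[[cn]] <- as.integer(v)
  }
  if (any(df$m < 1 | df$n < 1)) stop("sample sizes must be >= 1")
  dup <- duplicated(df$locus)
  if (any(dup)) stop("duplicate locus name: ", df$locus[which(dup)[1]])
  cl <- as.character(df$class)
  mapped <- .class_map[cl]
  df$class <- ifelse(!is.na(mapped), mapped,
                     ifelse(cl %in% .class_map, cl, "unknown"))
  attr(df, "source") <- path
  df
}

#' Write a counts table in the native dialect
#'
#' @param data counts data frame (internal column names).
#' @param path output path.
#' @return `path`, invisibly. Round-trips through [read_counts_table()].
#' @export
write_counts_table <- function(data, path) {
  inv <- setNames(names(.class_map), .class_map)
  out <- data.frame(M = data$m, N = data$n, Sf = data$Ks, Snp = data$Os,
                    Slp = data$Hs, Rf = data$Kr, Rnp = data$Or,
                    Rlp = data$Hr, Locus = data$locus,
                    Class = ifelse(data$class %in% names(inv),
                                   inv[data$class], data$class))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write/read posterior draws as delimited text
#' @param fit a [run_chain()] result (or its draw matrix).
#' @param path output path.
#' @return `path` invisibly / the draw matrix.
#' @export
write_draws <- function(fit, path) {
  m <- if (inherits(fit, "prf_draws")) fit$draws else as.matrix(fit)
  utils::write.table(as.data.frame(m), path, quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                              check.names = FALSE))
}

#' Write a run manifest (key-value text)
#' @param fit a [run_chain()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path) {
  cfg <- fit$config
  kv <- c(n_iter = cfg$n_iter, phase1 = cfg$phase1, phase2 = cfg$phase2,
          burn_in = cfg$burn_in, thin = cfg$thin, window_k = cfg$window_k,
          seed = cfg$seed, n_subchains = cfg$n_subchains,
          jump_scale = fit$jump_scale,
          setNames(round(fit$accept, 4), paste0("accept_", names(fit$accept))))
  writeLines(paste(names(kv), kv, sep = " = "), path)
  invisible(path)
}

.cli_usage <- function() {
  paste(c(
    "usage: tprf <command> [options]",
    "commands:",
    "  simulate --out PREFIX [--loci N] [--seed S] [--mu-gamma V] [--sigma-b V]",
    "           [--sigma-w V] [--t-div V]",
    "  fit      --data FILE --out PREFIX [--seed S] [--iterations N]",
    "           [--burn-in N] [--thin N] [--grid-points N] [--quad-order N]",
    "  summarize --draws FILE --data FILE --out FILE [--level P]",
    ""), collapse = "\n")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("missing value for option --", substring(a, 3))
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (writes a counts table plus a truth sidecar),
#' `fit` (runs the sampler on a table; writes draws plus a manifest) and
#' `summarize` (writes a summary table). Invoke via
#' `Rscript -e 'tprf::cli_main()' -- <command> ...` or the wrapper script in
#' `inst/cli/`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      message(.cli_usage())
      return(invisible(1L))
    }
    cmd <- args[1]
    opts <- .cli_opts(args[-1])
    seed <- as.integer(.cli_num(opts, "seed", 1))
    ctrl <- prf_control(
      grid_points = as.integer(.cli_num(opts, "grid_points", 150)),
      time_steps = as.integer(.cli_num(opts, "grid_points", 150)),
      gl_order = as.integer(.cli_num(opts, "quad_order", 64)),
      gh_order = as.integer(.cli_num(opts, "quad_order", 64)) %/% 4L)
    if (cmd == "simulate") {
      if (is.null(opts$out)) stop("simulate requires --out")
      des <- sim_design(
        L = as.integer(.cli_num(opts, "loci", 30)),
        global_truth = c(mu_gamma = .cli_num(opts, "mu_gamma", -6.82),
                         sigma_b = .cli_num(opts, "sigma_b", 3.78),
                         sigma_w = .cli_num(opts, "sigma_w", 2.56),
                         t_div = .cli_num(opts, "t_div", 4.38)),
        seed = seed)
      sim <- generate_dataset(des, ctrl)
      write_counts_table(sim$data, paste0(opts$out, "_counts.txt"))
      utils::write.table(sim$truth$loci, paste0(opts$out, "_truth.txt"),
                         quote = FALSE, row.names = FALSE, sep = "\t")
      writeLines(paste(names(des$global_truth),
                       unlist(des$global_truth), sep = " = "),
                 paste0(opts$out, "_truth_global.txt"))
      0L
    } else if (cmd == "fit") {
      if (is.null(opts$data) || is.null(opts$out))
        stop("fit requires --data and --out")
      data <- read_counts_table(opts$data)
      cfg <- chain_config(
        n_iter = as.integer(.cli_num(opts, "iterations", 20000)),
        burn_in = if (is.null(opts$burn_in)) NULL
                  else as.integer(opts$burn_in),
        thin = as.integer(.cli_num(opts, "thin", 10)),
        seed = seed)
      fit <- run_chain(data, prior_config(), cfg, ctrl)
      write_draws(fit, paste0(opts$out, "_draws.txt"))
      write_manifest(fit, paste0(opts$out, "_manifest.txt"))
      0L
    } else if (cmd == "summarize") {
      if (is.null(opts$draws) || is.null(opts$out))
        stop("summarize requires --draws and --out")
      m <- read_draws(opts$draws)
      s <- posterior_summary(m, level = .cli_num(opts, "level", 0.95))
      utils::write.table(s, opts$out, quote = FALSE, row.names = FALSE,
                         sep = "\t")
      0L
    } else {
      stop("unknown command: ", cmd)
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(.cli_usage())
    1L
  })
  invisible(as.integer(status))
}
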