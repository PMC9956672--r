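## End-to-end wiring: counts -> covariance statistics -> MC3 -> posterior
## outputs, plus the on-disk sample-log format used by the command line
## interface.

## one-line serialization of a graph (edge records joined by ';')
format_graph_line <- function(g) {
  paste(c(sprintf("@outgroup %s %.17g", g$outgroup, g$outgroup_length),
          vapply(seq_along(g$child), function(e) {
            base <- sprintf("%s,%s,%.17g", g$child[e], g$parent[e],
                            g$length[e])
            if (g$type[e] %in% c("main", "admix"))
              base <- sprintf("%s,%.17g,%s", base, g$prop[e], g$type[e])
            base
          }, "")),
        collapse = ";")
}

parse_graph_line <- function(line) {
  parts <- strsplit(line, ";", fixed = TRUE)[[1L]]
  hp <- strsplit(parts[1L], "\\s+")[[1L]]
  stopifnot(identical(hp[1L], "@outgroup"))
  body <- parts[-1L]
  child <- parent <- type <- character(length(body))
  len <- prop <- numeric(length(body))
  type[] <- "normal"; prop[] <- NA_real_
  for (i in seq_along(body)) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    child[i] <- f[1L]; parent[i] <- f[2L]; len[i] <- as.numeric(f[3L])
    if (length(f) == 5L) {
      prop[i] <- as.numeric(f[4L]); type[i] <- f[5L]
    }
  }
  new_graph(child, parent, len, type, prop, hp[2L], as.numeric(hp[3L]))
}

#' Write / read a posterior sample log
#'
#' The log is a TSV with one recorded state per line: iteration, log
#' posterior, log likelihood, number of admixture events, total branch
#' length, and the serialized graph. `save_posterior()` also writes a
#' `metadata.json` echoing the configuration, seed, acceptance rates and
#' swap rate, so a run is reproducible from its output directory alone.
#'
#' @param sample a `posterior_sample`.
#' @param dir output directory (created if missing).
#' @return `save_posterior()` returns `dir`; `load_posterior()` returns a
#'   `posterior_sample`.
#' @export
save_posterior <- function(sample, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- sample$stats
  st$graph <- vapply(sample$records, format_graph_line, "")
  utils::write.table(st, file.path(dir, "sample_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(config = sample$config[setdiff(names(sample$config),
                                              "betas")],
               betas = sample$config$betas,
               acceptance = as.list(sample$acceptance),
               swap_rate = sample$swap_rate,
               burnin_applied = sample$burnin_applied)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_posterior
#' @export
load_posterior <- function(dir) {
  st <- utils::read.table(file.path(dir, "sample_log.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  records <- lapply(st$graph, parse_graph_line)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  structure(list(records = records,
                 stats = st[setdiff(names(st), "graph")],
                 acceptance = unlist(meta$acceptance),
                 swap_rate = meta$swap_rate,
                 config = meta$config,
                 burnin_applied = meta$burnin_applied %||% 0),
            class = "posterior_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full inference pipeline on an allele-count dataset
#'
#' Computes the covariance statistics (S, B, h, bootstrap df, c_S) and
#' runs the Metropolis-coupled reversible-jump sampler. Refuses to start
#' when the estimated degrees of freedom do not exceed n-1 (the Wishart
#' likelihood would be undefined).
#'
#' @param counts an [allele_counts()] object or a count file path.
#' @param outgroup outgroup population label.
#' @param config an [mc3_config()].
#' @param bootstrap_reps,block_size bootstrap parameters for the df
#'   estimate.
#' @param df_override optional df value bypassing the bootstrap (testing
#'   hook).
#' @return List with `posterior` (a `posterior_sample`) and `cov` (the
#'   `covariance_estimate`).
#' @export
run_inference <- function(counts, outgroup, config = mc3_config(),
                          bootstrap_reps = 100L, block_size = 1000L,
                          df_override = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  cov <- covariance_estimate(counts, outgroup, R = bootstrap_reps,
                             block_size = block_size,
                             seed = config$seed, df = df_override)
  post <- mc3_run(cov, config = config)
  list(posterior = post, cov = cov)
}
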