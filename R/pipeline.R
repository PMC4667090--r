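#' End-to-end pipeline and command-line entry points
#'
#' Orchestrates simulate -> observe -> classify -> statistics -> HRM ->
#' RIL segregation with a single seed, writing TSV/JSON artifacts and a run
#' manifest so any run can be reproduced from its manifest alone.
#'
#' @name pipeline
NULL

#' Build a full run configuration
#'
#' @param sim named list of [sim_config()] arguments (at least `n_loci`).
#' @param ril named list of [ril_config()] arguments (`n_markers` is filled
#'   in from the discovered markers).
#' @param hrm named list: `noise_sd`, `threshold`, `delta`, `salt_offset`,
#'   `width`, `max_markers`.
#' @param seed global seed; propagated deterministically to every stage.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = list(n_loci = 50L), ril = list(), hrm = list(),
                       seed = 1L) {
  ril_defaults <- list(n_lines = 142L, selfing_generations = 6L, missing_rate = 0)
  hrm_defaults <- list(noise_sd = 0, threshold = 5, delta = 1.0,
                       salt_offset = 12, width = 0.8, max_markers = 3L)
  structure(list(
    sim = sim,
    ril = utils::modifyList(ril_defaults, ril),
    hrm = utils::modifyList(hrm_defaults, hrm),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(sim = as.list(x$sim), ril = as.list(x$ril), hrm = as.list(x$hrm),
             seed = x$seed %||% 1L)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# window of the carrying copy around a SNP, as the two allele amplicons
.marker_amplicons <- function(lm, snp_row, flank = 40L) {
  copy <- if (snp_row$copy %in% names(lm$a_copies)) lm$a_copies[[snp_row$copy]]
          else lm$b_copies[[snp_row$copy]]
  L <- nchar(copy)
  from <- max(1L, snp_row$position + 1L - flank)
  to <- min(L, snp_row$position + 1L + flank)
  ref_amp <- substring(copy, from, to)
  alt_amp <- ref_amp
  at <- snp_row$position + 1L - from + 1L
  substring(alt_amp, at, at) <- snp_row$alt
  c("1" = ref_amp, "2" = alt_amp)
}

#' Run the full pipeline into an output directory
#'
#' Stages: (1) simulate progenitors and tetraploid panel; (2) classify all
#' loci against truth; (3) marker statistics (Table-1-style report, densities,
#' class spectrum, per-fragment marker selection); (4) HRM genotyping of
#' selected markers; (5) RIL simulation from the two most divergent varieties
#' and 1:1 segregation tests. Outputs: `truth.tsv`, `variants.tsv`,
#' `compositions.tsv`, `marker_report.tsv`, `summary.json`, `hrm_calls.tsv`,
#' `segregation.tsv`, `manifest.json`. Identical configs give byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("tetrasnp")),
                   stages = character())
  fail <- function(stage, err) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop(err)
  }
  res <- list()

  tryCatch({
    sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
    cfg <- do.call(sim_config, sim_args)
    prog <- simulate_progenitors(cfg)
    panel <- simulate_tetraploid_panel(prog, cfg)
    write_truth_tsv(panel, file.path(out_dir, "truth.tsv"))
    res$panel <- panel
    manifest$stages <- c(manifest$stages, "simulate")
  }, error = function(e) fail("simulate", e))

  tryCatch({
    cls <- classify_panel(res$panel)
    write_variant_tsv(cls$variants, file.path(out_dir, "variants.tsv"))
    utils::write.table(cls$compositions, file.path(out_dir, "compositions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$classified <- cls
    manifest$stages <- c(manifest$stages, "classify")
  }, error = function(e) fail("classify", e))

  tryCatch({
    res$stats <- .pipeline_stats(res$panel, res$classified, out_dir)
    manifest$stages <- c(manifest$stages, "stats")
  }, error = function(e) fail("stats", e))

  tryCatch({
    res$hrm <- .pipeline_hrm(res$panel, res$classified, config, out_dir)
    manifest$stages <- c(manifest$stages, "hrm")
  }, error = function(e) fail("hrm", e))

  tryCatch({
    res$segregation <- .pipeline_ril(res$classified, config, out_dir)
    manifest$stages <- c(manifest$stages, "ril")
  }, error = function(e) fail("ril", e))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

.pipeline_stats <- function(panel, cls, out_dir) {
  v <- cls$variants
  src <- stats::setNames(vapply(panel$loci, `[[`, "", "source_class"),
                         vapply(panel$loci, `[[`, "", "locus_id"))
  snps <- v[v$category == "SNP", , drop = FALSE]
  markers <- if (nrow(snps)) data.frame(
    marker_id = sprintf("%s:%d", snps$locus_id, snps$pos_1based),
    group = unname(src[snps$locus_id]),
    variant_class = snps$collapsed_class,
    count1 = vapply(sprintf("%s:%d", snps$locus_id, snps$pos_1based),
                    function(k) sum(cls$calls[[k]] == 1L), 0L),
    count2 = vapply(sprintf("%s:%d", snps$locus_id, snps$pos_1based),
                    function(k) sum(cls$calls[[k]] == 2L), 0L),
    stringsAsFactors = FALSE) else NULL
  n_var <- length(panel$varieties)
  report <- if (!is.null(markers)) summarize_markers(markers, n_var) else NULL
  if (!is.null(report)) {
    utils::write.table(report$table, file.path(out_dir, "marker_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  seq_loci <- vapply(panel$loci, function(l) l$sequenceable, TRUE)
  total_bp <- sum(seq_loci) * panel$cfg$locus_length_bp
  dens <- lapply(c(SNP = "SNP", HSV = "HSV", PSV = "PSV"), function(cat) {
    n <- sum(v$category == cat)
    variant_density(n, total_bp, digits = if (cat == "SNP") 0L else 1L)
  })
  spectrum <- if (any(!is.na(v$collapsed_class))) class_spectrum(v) else NULL
  # per-fragment marker selection over fully linked SNP groups
  selected <- unlist(lapply(split(seq_len(nrow(snps)), snps$locus_id), function(ix) {
    frag <- lapply(ix, function(i) {
      k <- sprintf("%s:%d", snps$locus_id[i], snps$pos_1based[i])
      list(id = k, position = snps$pos_1based[i], calls = cls$calls[[k]])
    })
    tryCatch(marker_selection(frag), error = function(e) character())
  }), use.names = FALSE)
  summary <- list(
    n_loci_sequenced = sum(seq_loci), total_bp = total_bp,
    n_snp = sum(v$category == "SNP"), n_hsv = sum(v$category == "HSV"),
    n_psv = sum(v$category == "PSV"),
    n_unresolvable = sum(v$category == "unresolvable"),
    densities = lapply(dens, `[[`, "reported"),
    pic_summary = if (!is.null(report)) report$summary else NULL,
    spectrum = spectrum, selected_markers = selected)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(markers = markers, report = report, summary = summary)
}

.pipeline_hrm <- function(panel, cls, config, out_dir) {
  snps <- cls$variants[cls$variants$category == "SNP", , drop = FALSE]
  ids <- vapply(panel$loci, `[[`, "", "locus_id")
  rows <- list()
  n_done <- 0L
  if (nrow(snps)) for (i in seq_len(nrow(snps))) {
    if (n_done >= config$hrm$max_markers) break
    key <- sprintf("%s:%d", snps$locus_id[i], snps$pos_1based[i])
    lm <- panel$loci[[match(snps$locus_id[i], ids)]]
    sr <- lm$snp_table[lm$snp_table$position == snps$pos_1based[i] - 1L, , drop = FALSE]
    if (nrow(sr) != 1L) next
    amps <- .marker_amplicons(lm, sr[1, ])
    # GC-neutral substitutions have no Tm shift in the GC/length model
    if (abs(predict_tm(amps[["1"]], config$hrm$salt_offset) -
            predict_tm(amps[["2"]], config$hrm$salt_offset)) < 0.05) next
    calls <- cls$calls[[key]]
    genotypes <- lapply(as.character(calls), identity)
    names(genotypes) <- names(calls)
    gc <- hrm_genotype_panel(genotypes, amps, noise_sd = config$hrm$noise_sd,
                             threshold = config$hrm$threshold,
                             seed = config$seed + 2L, delta = config$hrm$delta,
                             salt_offset = config$hrm$salt_offset,
                             width = config$hrm$width)
    gc$marker_id <- key
    gc$true_allele <- unname(calls[gc$sample_id])
    rows[[key]] <- gc
    n_done <- n_done + 1L
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    data.frame(sample_id = character(), cluster = integer(),
               reference_distance = numeric(), marker_id = character(),
               true_allele = integer())
  utils::write.table(out, file.path(out_dir, "hrm_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

.pipeline_ril <- function(cls, config, out_dir) {
  calls <- cls$calls
  empty <- data.frame(marker_id = character(), allele1 = character(),
                      allele2 = character(), n1 = integer(), n2 = integer(),
                      chi2 = numeric(), p = numeric(), distorted = logical())
  if (length(calls) < 1L) {
    utils::write.table(empty, file.path(out_dir, "segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(empty)
  }
  mat <- do.call(cbind, calls)  # varieties x markers
  # parents: variety 1 and the variety most divergent from it
  dif <- apply(mat, 1L, function(r) sum(r != mat[1, ]))
  p2 <- which.max(dif)
  if (dif[p2] == 0L) {
    utils::write.table(empty, file.path(out_dir, "segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    return(empty)
  }
  rcfg <- do.call(ril_config, utils::modifyList(
    list(n_markers = ncol(mat), seed = config$seed + 3L), config$ril))
  ril <- simulate_ril(stats::setNames(as.character(mat[1, ]), colnames(mat)),
                      stats::setNames(as.character(mat[p2, ]), colnames(mat)),
                      rcfg)
  seg <- segregation_tests(ril)
  utils::write.table(seg, file.path(out_dir, "segregation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  seg
}

#' Recompute PIC values for a published-style marker count table
#'
#' Reads a TSV with columns `marker_id`, `variant_class`, `count1`, `count2`
#' and optionally a published PIC column, recomputes PIC with the full-panel
#' denominator, and reports agreement row by row.
#'
#' @param table path to the TSV, or an equivalent data.frame. The marker
#'   table shipped with the package (`system.file("extdata",
#'   "table1_markers.tsv", package = "tetrasnp")`) is in this format.
#' @param panel_size denominator (default 96).
#' @param expected_col name of the published-PIC column to compare against
#'   (default `"pic_published"`; skipped when absent).
#' @return data.frame with computed `pic` (3 decimals) and, when available,
#'   `pic_published` and logical `match`.
#' @export
reproduce_table1 <- function(table, panel_size = 96L,
                             expected_col = "pic_published") {
  df <- if (is.data.frame(table)) table else
    utils::read.delim(table, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(marker_id = character(), variant_class = character(),
                      count1 = integer(), count2 = integer(), pic = numeric()))
  }
  need <- c("marker_id", "count1", "count2")
  if (!all(need %in% names(df))) {
    stop("missing required columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(!is.finite(df$count1) | !is.finite(df$count2) |
                 df$count1 < 0 | df$count2 < 0 |
                 df$count1 + df$count2 > panel_size)
  if (length(bad)) {
    stop("invalid counts in rows (1-based, excluding header): ",
         paste(bad, collapse = ", "))
  }
  df$pic <- vapply(seq_len(nrow(df)), function(i) {
    pic(c(df$count1[i], df$count2[i]), panel_size)$pic_3dp
  }, 0)
  if (expected_col %in% names(df)) {
    df$match <- abs(df$pic - df[[expected_col]]) < 5e-4
  }
  df
}

#' Command-line interface
#'
#' Subcommands: `run` (full pipeline), `table1` (recompute a PIC table).
#' Flags: `--config <json>`, `--seed <int>`, `--out <dir>`, and for `table1`
#' a positional TSV path. Intended for
#' `Rscript -e 'tetrasnp::tetrasnp_cli()' <subcommand> ...`.
#'
#' @param args character vector (default: command-line arguments).
#' @return exit status, invisibly.
#' @export
tetrasnp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: run --out DIR [--config FILE] [--seed N] | table1 TSV [--out FILE]"
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  get_opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1] + 1L] else default
  }
  if (cmd == "run") {
    out <- get_opt("--out"); if (is.null(out)) stop(usage)
    seed <- as.integer(get_opt("--seed", "1"))
    cfgf <- get_opt("--config")
    config <- if (is.null(cfgf)) run_config(seed = seed) else {
      cf <- read_run_config(cfgf); cf$seed <- seed; cf
    }
    run_pipeline(config, out)
    message("pipeline written to ", out)
  } else if (cmd == "table1") {
    pos <- setdiff(args, c("--out", get_opt("--out", character())))
    pos <- pos[!startsWith(pos, "--")]
    if (!length(pos)) stop(usage)
    res <- reproduce_table1(pos[1])
    out <- get_opt("--out")
    if (is.null(out)) {
      print(res)
    } else {
      utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  } else stop("unknown subcommand: ", cmd, "\n", usage)
  invisible(0L)
}
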