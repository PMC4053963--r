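#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file) with an `out_dir`, a
#' `seed`, and either a `simulate` block (parameter overrides for
#' [sim_params()]) or an `inputs` block of file paths (`contigs`: named
#' sample -> BED9 path; `genes`: BED; `promoters`: named line -> BED;
#' optional `repeats`, `blacklist`, `chrom_sizes`). Optional `caller` and
#' `quant` blocks override [caller_params()] / [quant_params()].
#'
#' @param config a named list or path to a YAML file.
#' @return the validated config (class `vlinc_run_config`), invisibly
#'   normalized.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("config needs a 'simulate' or an 'inputs' block")
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs[c("contigs", "genes", "promoters",
                                    "repeats", "blacklist", "chrom_sizes")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  config$caller <- do.call(caller_params, as.list(config$caller))
  config$quant <- do.call(quant_params, as.list(config$quant))
  class(config) <- c("vlinc_run_config", "list")
  config
}

.config_fingerprint <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

.out_header <- function(config) {
  sprintf("# vlincscan %s; config=%s; seed=%s",
          as.character(utils::packageVersion("vlincscan")),
          .config_fingerprint(config), config$seed)
}

.write_headed <- function(writer, obj, path, header) {
  tmp <- paste0(path, ".tmp")
  writer(obj, tmp)
  writeLines(c(header, readLines(tmp)), path)
  unlink(tmp)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> call -> annotate -> enrich -> quantify ->
#' report. Every output file carries a header comment with the tool version,
#' a config fingerprint and the seed; a rerun with the same config is
#' bit-identical. A machine-readable `summary.json` with per-stage counts is
#' written to the run directory.
#'
#' @param config a run configuration (see [validate_run_config()]).
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .out_header(config)
  log <- function(stage, ...) message("[", stage, "] ", ...)
  summary <- list(seed = config$seed,
                  config_fingerprint = .config_fingerprint(config))

  stage <- "simulate"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      sp <- do.call(sim_params, c(list(seed = config$seed),
                                  as.list(config$simulate)))
      sim <- simulate_annotation(sp)
      contigs <- emit_contigs(sim)
      genes <- sim$genes
      promoters_by_line <- sim$promoters_by_line
      repeats <- sim$repeats
      blacklist <- sim$blacklist
      genome <- sim$genome
      log(stage, length(sim$vlincs), " regions planted")
      summary$simulate <- list(planted = length(sim$vlincs),
                               genes = length(genes))
      .write_headed(write_chrom_sizes, genome,
                    file.path(config$out_dir, "chrom.sizes"), hdr)
      .write_headed(write_bed, genes,
                    file.path(config$out_dir, "genes.bed"), hdr)
      utils::write.table(sim$truth,
                         file.path(config$out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      inp <- config$inputs
      genome <- if (!is.null(inp$chrom_sizes))
        read_chrom_sizes(inp$chrom_sizes) else NULL
      contigs <- lapply(inp$contigs, read_contigs, genome = genome)
      genes <- read_bed(inp$genes, genome = genome)
      promoters_by_line <- mapply(read_promoters, inp$promoters,
                                  names(inp$promoters),
                                  MoreArgs = list(genome = genome),
                                  SIMPLIFY = FALSE)
      repeats <- if (!is.null(inp$repeats))
        read_repeats(inp$repeats, genome = genome) else
          GenomicRanges::GRanges()
      blacklist <- if (!is.null(inp$blacklist))
        read_bed(inp$blacklist, genome = genome) else
          GenomicRanges::GRanges()
      sim <- NULL
    }

    stage <- "call"
    called <- lapply(names(contigs), function(s)
      call_from_contigs(contigs[[s]], genes, config$caller, sample = s))
    names(called) <- names(contigs)
    for (s in names(called))
      .write_headed(write_bed, called[[s]],
                    file.path(config$out_dir,
                              sprintf("vlincs.%s.bed", s)), hdr)
    summary$call <- lapply(called, length)
    log(stage, sum(unlist(summary$call)), " regions called")

    stage <- "annotate"
    assignments <- list()
    for (s in names(called)) {
      if (!s %in% names(promoters_by_line)) next
      prom <- classify_promoter_repeats(promoters_by_line[[s]], repeats)
      assignments[[s]] <- assign_promoters_to_vlincs(called[[s]], prom)
      utils::write.table(
        assignments[[s]],
        file.path(config$out_dir, sprintf("promoters.%s.tsv", s)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$annotate <- lapply(assignments, function(a)
      list(with_promoter = sum(a$any_promoter),
           ltr_driven = sum(a$ltr_driven %in% TRUE)))

    stage <- "enrich"
    if (!is.null(genome)) {
      enr <- list()
      for (s in names(called)) {
        if (!s %in% names(promoters_by_line) || !length(called[[s]])) next
        enr[[s]] <- as.data.frame(test_promoter_overlap_stranded(
          called[[s]], promoters_by_line[[s]], genes, blacklist, genome))
      }
      if (length(enr)) {
        tab <- do.call(rbind, enr)
        tab <- cbind(sample = names(enr), tab)
        # raw p-values are the primary output; the corrected column is
        # informational and never gates anything
        tab$p_bonferroni <- pmin(1, tab$p_value * nrow(tab))
        utils::write.table(tab, file.path(config$out_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        summary$enrich <- stats::setNames(
          lapply(enr, function(e) list(n = e$n, fold = e$fold,
                                       log10_p = e$log10_p)), names(enr))
      }
    }

    stage <- "quantify"
    all_called <- do.call(c, unname(called))
    if (length(all_called)) {
      groups <- if (!is.null(sim)) sim$params$cell_lines else config$groups
      mat <- quantify(contigs, all_called, config$quant, groups = groups)
      utils::write.table(
        data.frame(region = rownames(mat), mat, check.names = FALSE),
        file.path(config$out_dir, "expression.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      summary$quantify <- list(regions = nrow(mat), samples = ncol(mat))
    }

    stage <- "report"
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summary
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
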