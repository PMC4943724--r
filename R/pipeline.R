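#' Default pipeline configuration
#'
#' Returns the full configuration list with every threshold at its default
#' (QC: sample call rate > 0.90, marker call rate >= 0.95, MAF >= 0.02;
#' weights: c = 0.5, minimum accuracy 0.50; meta: f = 0.05; VEGAS: 100 kb
#' windows, r2 <= 0.5, listing p < 0.01, >= 4 traits). User values are
#' merged over these defaults.
#'
#' @param ... named overrides, or a single list (e.g. from
#'   \code{yaml::read_yaml}) to merge.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    paths = list(plink_prefix = NULL, trait_files = NULL,
                 gene_annotation = NULL, gene_dialect = "1-based"),
    traits = list(h2 = NULL),          # named vector: trait id -> h2
    qc = list(min_sample_call = 0.90, min_marker_call = 0.95,
              min_maf = 0.02, autosomes = NULL),
    weights = list(c = 0.5, min_accuracy = 0.50, accuracy_on = "accuracy"),
    lmm = list(grm_method = "vanraden1", per_loco_reml = TRUE,
               tol = 1e-8),
    meta = list(f = 0.05, diag_mode = "signed"),
    vegas = list(expand_bp = 100000, max_r2 = 0.5, list_alpha = 0.01,
                 min_traits = 4, k_init = 1000, max_sims = 1e6,
                 exclude_genes = character(0),
                 exclude_chroms = character(0),
                 except_genes = character(0)),
    seed = 1L)
  ov <- list(...)
  if (length(ov) == 1 && is.null(names(ov)) && is.list(ov[[1]])) ov <- ov[[1]]
  mergeConfig(defaults, ov)
}

mergeConfig <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the keys of
#'   \code{\link{pipelineConfig}}.
#' @return merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  pipelineConfig(yaml::read_yaml(path))
}

#' Cross-trait correlation report (Table-1 style)
#'
#' Pearson correlation matrices of dEBVs (pairwise-complete across the
#' animals shared by each trait pair) and of genome-wide signed t-values,
#' plus the upper-triangle off-diagonal means of both -- the two summary
#' statistics used as proxies for the additive genetic correlations.
#'
#' @param traits named list of \code{\linkS4class{TraitData}} (after the
#'   accuracy filter).
#' @param assocTables named list of per-trait association tables sharing one
#'   marker set.
#' @return list: \code{debv_corr}, \code{tvalue_corr},
#'   \code{mean_offdiag_debv}, \code{mean_offdiag_t}.
#' @export
correlationReport <- function(traits, assocTables) {
  q <- length(traits)
  if (q < 2) stop("need at least 2 traits")
  ids <- sort(unique(unlist(lapply(traits, function(tr) records(tr)$animal_id))))
  debv <- sapply(traits, function(tr) {
    r <- records(tr)
    r$debv[match(ids, r$animal_id)]
  })
  dc <- cor(debv, use = "pairwise.complete.obs")
  tc <- tvalueCorrelation(assocTables)$C_raw
  list(debv_corr = dc, tvalue_corr = tc,
       mean_offdiag_debv = meanOffdiagonal(dc),
       mean_offdiag_t = meanOffdiagonal(tc))
}

#' Run the whole pleiotropy-mapping pipeline
#'
#' Orchestrates: genotype input and QC, per-trait weighting and accuracy
#' filtering, LOCO GRMs, per-trait genome scans, the correlation report,
#' multi-trait meta-analysis with the empirical FDR threshold, per-trait
#' gene-based scans, and the pleiotropic-gene call. All tables are written
#' as TSV into \code{outDir} along with a JSON run manifest recording
#' seeds, thresholds and filter counts. The run is deterministic given the
#' config and seed.
#'
#' @param config configuration list (see \code{\link{pipelineConfig}}) or a
#'   path to a YAML file.
#' @param outDir output directory, created if needed.
#' @param seed optional override of \code{config$seed}.
#' @return invisibly, a list with all in-memory stage results.
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  else config <- pipelineConfig(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage: ", name),
                 file.path(outDir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  tsv <- function(df, name)
    write.table(df, file.path(outDir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)

  ## genotypes + QC
  gm0 <- stage("read_genotypes", {
    if (is.null(config$paths$plink_prefix))
      stop("config paths$plink_prefix is required")
    readPlink(config$paths$plink_prefix)
  })
  qc <- stage("genotype_qc",
    genotypeQc(gm0, config$qc$min_sample_call, config$qc$autosomes,
               config$qc$min_marker_call, config$qc$min_maf))
  gm <- qc$genotypes
  tsv(qc$report, "qc_report.tsv")
  gaps <- stage("gap_summary", gapSummary(markerMap(gm)))

  ## traits
  traits <- stage("trait_input", {
    tf <- config$paths$trait_files
    if (is.null(tf)) stop("config paths$trait_files is required")
    h2 <- unlist(config$traits$h2)
    out <- list()
    for (nm in names(tf)) {
      if (!file.exists(tf[[nm]])) stop("trait file not found: ", tf[[nm]])
      if (is.null(h2[[nm]])) stop("no h2 configured for trait ", nm)
      tr <- readTraitTable(tf[[nm]], traitId = nm, h2 = h2[[nm]],
                           c = config$weights$c)
      tr <- accuracyFilter(tr, config$weights$min_accuracy,
                           on = config$weights$accuracy_on)
      rec <- records(tr)
      keep <- rec$animal_id %in% sampleIds(gm)
      tr@records <- rec[keep, , drop = FALSE]
      validObject(tr)
      out[[nm]] <- tr
    }
    out
  })
  for (nm in names(traits))
    tsv(records(traits[[nm]]), paste0("weights_", nm, ".tsv"))

  ## LOCO scans
  grms <- stage("loco_grms", computeLocoGrms(gm))
  assoc <- stage("gwa_loco", {
    out <- list()
    for (nm in names(traits)) {
      a <- gwaLoco(gm, traits[[nm]], grms,
                   perLocoReml = isTRUE(config$lmm$per_loco_reml))
      a$trait_id <- nm
      out[[nm]] <- a
      tsv(a[, c("marker_id", "chrom", "bp", "allele", "b", "se", "t", "p")],
          paste0("assoc_", nm, ".tsv"))
    }
    out
  })

  ## correlation report
  correp <- stage("correlation_report", correlationReport(traits, assoc))
  tsv(as.data.frame(correp$debv_corr), "corr_debv.tsv")
  tsv(as.data.frame(correp$tvalue_corr), "corr_tvalues.tsv")

  ## meta-analysis + FDR
  meta <- stage("meta_analysis", {
    C <- tvalueCorrelation(assoc, diagMode = config$meta$diag_mode)
    tmat <- vapply(assoc, function(a) a$t, numeric(nrow(assoc[[1]])))
    flagged <- Reduce(`|`, lapply(assoc, function(a) !is.na(a$flag)))
    ms <- metaStatistic(tmat[!flagged, , drop = FALSE], C)
    fdr <- selectFdrThreshold(ms$p, f = config$meta$f)
    tab <- cbind(markerMap(gm)[!flagged, c("marker_id", "chrom", "bp")],
                 stat = ms$stat, p = ms$p, neglog10p = -log10(ms$p),
                 significant = fdr$significant)
    tsv(tab, "meta.tsv")
    list(C = C, table = tab, fdr = fdr)
  })

  ## VEGAS + pleiotropy call
  genes <- stage("gene_annotation", {
    if (is.null(config$paths$gene_annotation))
      stop("config paths$gene_annotation is required")
    g <- readGeneAnnotation(config$paths$gene_annotation,
                            dialect = config$paths$gene_dialect)
    assignMarkers(g, markerMap(gm), expandBp = config$vegas$expand_bp)
  })
  vegas <- stage("vegas", {
    out <- list()
    for (nm in names(traits)) {
      v <- geneScan(assoc[[nm]], genes, gm, seed = config$seed,
                    expandBp = config$vegas$expand_bp,
                    maxR2 = config$vegas$max_r2,
                    kInit = config$vegas$k_init,
                    kMax = config$vegas$max_sims)
      out[[nm]] <- v
      tsv(v[, setdiff(names(v), "members")], paste0("vegas_", nm, ".tsv"))
    }
    out
  })
  calls <- stage("pleiotropy_call",
    callPleiotropic(vegas, minTraits = config$vegas$min_traits,
                    listAlpha = config$vegas$list_alpha,
                    excludeGenes = config$vegas$exclude_genes,
                    excludeChroms = config$vegas$exclude_chroms,
                    exceptGenes = config$vegas$except_genes))
  tsv(calls, "pleiotropy_calls.tsv")

  manifest <- list(
    seed = config$seed,
    thresholds = list(qc = config$qc, weights = config$weights,
                      meta_f = config$meta$f, vegas = config$vegas[
                        c("expand_bp", "max_r2", "list_alpha", "min_traits")]),
    counts = list(
      samples_in = nSamples(gm0), markers_in = nMarkers(gm0),
      samples_qc = nSamples(gm), markers_qc = nMarkers(gm),
      records_per_trait = vapply(traits, function(tr) nrow(records(tr)),
                                 integer(1)),
      meta_significant = sum(meta$fdr$significant),
      meta_alpha = meta$fdr$alpha,
      candidates = sum(calls$is_candidate)),
    gap_summary = as.list(gaps),
    mean_offdiag = list(debv = correp$mean_offdiag_debv,
                        tvalues = correp$mean_offdiag_t))
  writeLines(asJson(manifest), file.path(outDir, "manifest.json"))
  invisible(list(genotypes = gm, qc = qc$report, traits = traits,
                 assoc = assoc, correlation = correp, meta = meta,
                 vegas = vegas, calls = calls, manifest = manifest))
}

# minimal JSON writer for the manifest (scalars, vectors, nested lists)
asJson <- function(x, indent = "") {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.list(x)) {
    if (is.null(names(x)))
      return(paste0("[", paste(vapply(x, asJson, character(1)),
                               collapse = ", "), "]"))
    inner <- vapply(names(x), function(nm)
      paste0(indent, '  "', esc(nm), '": ', asJson(x[[nm]], paste0(indent, "  "))),
      character(1))
    return(paste0("{\n", paste(inner, collapse = ",\n"), "\n", indent, "}"))
  }
  if (length(x) != 1) {
    return(paste0("[", paste(vapply(seq_along(x), function(i)
      asJson(x[i]), character(1)), collapse = ", "), "]"))
  }
  if (is.character(x)) paste0('"', esc(x), '"')
  else if (is.logical(x)) tolower(as.character(x))
  else format(x, digits = 15, scientific = FALSE, trim = TRUE)
}
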