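# Catalogue FASTA + SNP-sidecar / depth-table readers and writers, YAML
# configuration, and the end-to-end workflow driver.

#' Write a locus catalogue (FASTA + SNP sidecar TSV)
#'
#' @param cat locus_catalog.
#' @param fasta path for the tag FASTA (record id = locus_id).
#' @param snp_tsv path for the SNP sidecar (locus_id, position, alleles).
#' @return invisibly, the two paths.
#' @export
write_catalog <- function(cat, fasta, snp_tsv) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(cat$loci$tag,
                                                   cat$loci$locus_id))
  Biostrings::writeXStringSet(seqs, fasta)
  data.table::fwrite(cat$snps[c("locus_id", "position", "alleles")],
                     snp_tsv, sep = "\t")
  invisible(c(fasta, snp_tsv))
}

#' Read a locus catalogue (FASTA + SNP sidecar TSV)
#'
#' @param fasta tag FASTA.
#' @param snp_tsv SNP sidecar TSV (locus_id, position, alleles); optional.
#' @param pipeline label to attach.
#' @return locus_catalog.
#' @export
read_catalog <- function(fasta, snp_tsv = NULL, pipeline = "catalog") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  loci <- data.frame(locus_id = names(seqs),
                     tag = unname(as.character(seqs)),
                     stringsAsFactors = FALSE)
  snps <- if (!is.null(snp_tsv)) {
    as.data.frame(data.table::fread(snp_tsv, colClasses = list(
      character = "locus_id", integer = "position", character = "alleles")))
  } else NULL
  locus_catalog(loci, snps, pipeline)
}

#' Write a depth matrix as TSV
#'
#' Long format: sample, locus_id, position, nA, nC, nG, nT. Sites absent
#' from the pipeline's catalogue (NA counts) are omitted.
#'
#' @param dm depth_matrix.
#' @param snps data.frame mapping the depth columns (snp_id, locus_id,
#'   position) -- e.g. a genotype matrix's snps table.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
write_depth_tsv <- function(dm, snps, path) {
  counts <- dm$counts
  ns <- dim(counts)[1]; nl <- dim(counts)[2]
  idx <- match(dimnames(counts)[[2]], snps$snp_id)
  dt <- data.frame(
    sample = rep(dimnames(counts)[[1]], nl),
    locus_id = rep(snps$locus_id[idx], each = ns),
    position = rep(snps$position[idx], each = ns),
    nA = as.vector(counts[, , 1]), nC = as.vector(counts[, , 2]),
    nG = as.vector(counts[, , 3]), nT = as.vector(counts[, , 4]),
    stringsAsFactors = FALSE)
  data.table::fwrite(dt[!is.na(dt$nA), ], path, sep = "\t")
  invisible(path)
}

#' Read a depth TSV back into a depth_matrix
#'
#' @param path TSV written by \code{\link{write_depth_tsv}}.
#' @param samples optional sample universe (rows); defaults to those present.
#' @param pipeline label.
#' @return depth_matrix (sites missing for a sample become NA).
#' @export
read_depth_tsv <- function(path, samples = NULL, pipeline = "pipeline") {
  dt <- data.table::fread(path)
  sid <- snp_id(dt$locus_id, dt$position)
  usid <- unique(sid)
  if (is.null(samples)) samples <- unique(dt$sample)
  counts <- array(NA_integer_, c(length(samples), length(usid), 4),
                  dimnames = list(samples, usid, NUC))
  i <- match(dt$sample, samples); j <- match(sid, usid)
  counts[cbind(i, j, 1L)] <- dt$nA
  counts[cbind(i, j, 2L)] <- dt$nC
  counts[cbind(i, j, 3L)] <- dt$nG
  counts[cbind(i, j, 4L)] <- dt$nT
  depth_matrix(counts, pipeline)
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; recognised keys are the \code{\link{sim_config}}
#' arguments plus filter thresholds (\code{min_coverage}, \code{max_snps},
#' \code{mac}, \code{pop_max_missing}, \code{hwe_alpha}), the clustering
#' mismatch limit \code{cluster_mismatch} and \code{n_boot}.
#'
#' @param path YAML file (may be NULL for all-defaults).
#' @param overrides named list applied on top of the file.
#' @return list with elements \code{sim} (sim_config), \code{filters},
#'   \code{cluster_mismatch}, \code{n_boot}.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  raw <- utils::modifyList(raw, overrides)
  sim_keys <- names(formals(sim_config))
  filt_keys <- c("min_coverage", "max_snps", "mac", "pop_max_missing",
                 "hwe_alpha")
  other_keys <- c("cluster_mismatch", "n_boot")
  unknown <- setdiff(names(raw), c(sim_keys, filt_keys, other_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  simargs <- raw[intersect(names(raw), sim_keys)]
  if (!is.null(simargs$pipelines)) {
    simargs$pipelines <- lapply(simargs$pipelines, function(p) {
      utils::modifyList(list(read_loss = 0, locus_dropout = 0, oversplit = 0,
                             flip = 0), p)
    })
  }
  m <- raw$cluster_mismatch
  if (!is.null(m) && !(m %in% 0:10)) stop("cluster_mismatch out of range")
  list(sim = do.call(sim_config, simargs),
       filters = raw[intersect(names(raw), filt_keys)],
       cluster_mismatch = if (is.null(m)) 2L else as.integer(m),
       n_boot = if (is.null(raw$n_boot)) 1000L else as.integer(raw$n_boot))
}

#' Run the full two-pipeline workflow
#'
#' Simulate (or accept pre-built pipeline outputs), run the filter cascade
#' per pipeline with a step-6 checkpoint, reconcile the catalogues, build
#' the COM and MER panels, quantify genotype concordance and missing-data
#' sources, and summarise the population-genomic metrics of the four panels.
#' When \code{out_dir} is given, all artifacts are written there (GENEPOP
#' panels, audit/cluster/concordance/metrics TSVs and a manifest recording
#' every threshold and seed).
#'
#' @param config list from \code{\link{load_run_config}} (or NULL for
#'   defaults).
#' @param out_dir optional artifact directory (created if needed).
#' @param sim optional pre-built result of \code{\link{build_pipeline_outputs}}.
#' @param quiet suppress progress messages.
#' @return list with panels, audits, cluster map, concordance, missing-source
#'   and metrics tables.
#' @export
run_full <- function(config = NULL, out_dir = NULL, sim = NULL,
                     quiet = FALSE) {
  if (is.null(config)) config <- load_run_config(NULL)
  say <- function(...) if (!quiet) message("[radpanels] ", sprintf(...))
  if (is.null(sim)) {
    say("simulating dataset (seed %d)", config$sim$seed)
    sim <- build_pipeline_outputs(config$sim)
  }
  pnames <- names(sim$pipelines)
  stopifnot(length(pnames) == 2)

  cascade <- function(pn) {
    pl <- sim$pipelines[[pn]]
    say("filter cascade: %s", pn)
    full <- run_cascade(pl$genotypes, pl$depths, pl$catalog, config$filters)
    step6 <- run_cascade(pl$genotypes, pl$depths, pl$catalog, config$filters,
                         stop_after_step = 6)
    list(panel = full$panel, audit = full$audit, step6 = step6$panel)
  }
  ca <- cascade(pnames[1]); cb <- cascade(pnames[2])

  say("reconciling catalogues (m = %d)", config$cluster_mismatch)
  cm <- cluster_catalogs(sim$pipelines[[1]]$catalog,
                         sim$pipelines[[2]]$catalog,
                         m = config$cluster_mismatch)
  com <- build_com_panel(cm, ca$step6, cb$step6)
  mer <- build_mer_panel(cm, ca$step6, cb$step6, com)
  conc <- compare_panels(com$A, com$B)
  miss <- attribute_missing(com$A, com$B, sim$pipelines[[1]]$depths,
                            sim$pipelines[[2]]$depths, com$map)

  say("population-genomic metrics")
  seed <- config$sim$seed
  panels <- list(com$A, mer)
  names(panels) <- c("COM", "MER")
  panels[[pnames[1]]] <- ca$panel
  panels[[pnames[2]]] <- cb$panel
  panels <- panels[c(pnames, "COM", "MER")]
  metrics <- lapply(panels, function(p) {
    if (n_snps(p) >= 2) summarize_panel(p, n_boot = config$n_boot,
                                        seed = seed) else NULL
  })

  res <- list(config = config, sim = sim, panels = panels,
              audits = stats::setNames(list(ca$audit, cb$audit), pnames),
              cluster_map = cm, com = com, mer = mer,
              concordance = conc, missing_sources = miss, metrics = metrics)
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

# Serialise every table of a run into an artifact directory.
write_run_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  for (pn in names(res$panels)) {
    write_genepop(res$panels[[pn]], fp(sprintf("panel_%s.genepop", pn)))
  }
  for (pn in names(res$audits)) {
    data.table::fwrite(as.data.frame(res$audits[[pn]]),
                       fp(sprintf("audit_%s.tsv", pn)), sep = "\t")
    miss <- attr(res$audits[[pn]], "per_sample_missing_after_mincov")
    data.table::fwrite(data.frame(sample = names(miss),
                                  missing_fraction = as.numeric(miss)),
                       fp(sprintf("missing_after_mincov_%s.tsv", pn)),
                       sep = "\t")
  }
  data.table::fwrite(res$cluster_map$members, fp("clusters.tsv"), sep = "\t")
  data.table::fwrite(res$concordance$table, fp("concordance.tsv"), sep = "\t")
  data.table::fwrite(res$missing_sources$table, fp("missing_sources.tsv"),
                     sep = "\t")
  mt <- do.call(rbind, lapply(names(res$metrics), function(pn) {
    m <- res$metrics[[pn]]
    if (is.null(m)) return(NULL)
    cbind(panel = pn, m$per_pop, global_fst = m$global_fst)
  }))
  if (!is.null(mt)) data.table::fwrite(mt, fp("metrics.tsv"), sep = "\t")
  manifest <- list(
    package_version = as.character(utils::packageVersion("radpanels")),
    seed = res$config$sim$seed,
    sim = res$config$sim[setdiff(names(res$config$sim), "snps_per_locus_dist")],
    snps_per_locus_dist = as.numeric(res$config$sim$snps_per_locus_dist),
    filters = attr(res$audits[[1]], "params"),
    cluster_mismatch = res$config$cluster_mismatch,
    n_boot = res$config$n_boot,
    concordance_direction = sprintf("X->Y means X in %s, Y in %s",
                                    res$concordance$panels[1],
                                    res$concordance$panels[2]))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
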