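# Cross-catalogue RAD-locus reconciliation: greedy Hamming-threshold
# clustering of the pooled, canonically oriented tags of two catalogues
# (equal-length ungapped tags reduce cd-hit-est with -c (L-m)/L, -b 1, -g 1
# to exactly this), then SNP matching inside shared clusters and the
# construction of the common (COM) and merged (MER) panels.

#' Hamming distance between equal-length tags
#'
#' @param a,b character scalars (or equal-length vectors recycled pairwise).
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (any(nchar(a) != nchar(b))) stop("unequal tag lengths")
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Greedy best-match clustering of two catalogues
#'
#' Tags from both catalogues are canonically oriented and processed in a
#' deterministic order (canonical tag, then pipeline label, then locus id).
#' Each tag joins the best-matching existing cluster representative (minimum
#' mismatches, ties to the earliest representative) when that minimum is at
#' most \code{m}; otherwise it founds a new cluster. A cluster containing
#' loci from both catalogues is SHARED, otherwise PRIVATE.
#'
#' @param catA,catB locus_catalog objects with the same tag length.
#' @param m maximum mismatches (2 for fish-like, 3 for bivalve-like panels).
#' @return object of class \code{cluster_map}: data.frame \code{members}
#'   (cluster, pipeline, locus_id, flipped, mismatches, representative) and
#'   \code{clusters} (cluster, shared).
#' @export
cluster_catalogs <- function(catA, catB, m = 2) {
  stopifnot(m >= 0)
  if (!identical(catA$L, catB$L)) stop("catalogues have different tag lengths")
  L <- catA$L
  tags <- c(catA$loci$tag, catB$loci$tag)
  pipe <- c(rep(catA$pipeline, nrow(catA$loci)),
            rep(catB$pipeline, nrow(catB$loci)))
  ids <- c(catA$loci$locus_id, catB$loci$locus_id)
  ctags <- canonical_orientation(tags)
  flipped <- attr(ctags, "flipped")
  ord <- order(ctags, pipe, ids, method = "radix")

  n <- length(tags)
  enc <- matrix(0L, L, n)
  for (i in seq_len(n)) enc[, i] <- match(strsplit(ctags[i], "",
                                                   fixed = TRUE)[[1]], NUC)
  cluster <- integer(n)
  mism <- integer(n)
  rep_cols <- integer(0)                 # encoded columns of representatives
  for (k in ord) {
    if (length(rep_cols)) {
      d <- colSums(enc[, rep_cols, drop = FALSE] != enc[, k])
      best <- which.min(d)               # ties -> earliest representative
      if (d[best] <= m) {
        cluster[k] <- best
        mism[k] <- d[best]
        next
      }
    }
    rep_cols <- c(rep_cols, k)
    cluster[k] <- length(rep_cols)
    mism[k] <- 0L
  }
  members <- data.frame(cluster = cluster, pipeline = pipe, locus_id = ids,
                        flipped = flipped, mismatches = mism,
                        representative = seq_len(n) %in% rep_cols,
                        stringsAsFactors = FALSE)
  members <- members[order(members$cluster, members$pipeline,
                           members$locus_id), ]
  rownames(members) <- NULL
  shared <- tapply(members$pipeline, members$cluster,
                   function(p) length(unique(p)) == 2)
  clusters <- data.frame(cluster = as.integer(names(shared)),
                         shared = as.logical(shared))
  structure(list(members = members, clusters = clusters,
                 pipelines = c(catA$pipeline, catB$pipeline), m = m, L = L),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map %s vs %s, m = %d> %d clusters (%d shared, %d private)\n",
              x$pipelines[1], x$pipelines[2], x$m, nrow(x$clusters),
              sum(x$clusters$shared), sum(!x$clusters$shared)))
  invisible(x)
}

# Locus -> (cluster, flipped) lookup for one pipeline.
.locus_lookup <- function(cm, pipeline) {
  mb <- cm$members[cm$members$pipeline == pipeline, ]
  stats::setNames(split(mb[c("cluster", "flipped")], seq_len(nrow(mb))),
                  mb$locus_id)
}

# Canonicalised SNP table of a step-6 panel: cluster, canonical position and
# canonical allele pair per SNP column.
.canonical_snps <- function(panel, cm, pipeline) {
  mb <- cm$members[cm$members$pipeline == pipeline, ]
  ix <- match(panel$snps$locus_id, mb$locus_id)
  ok <- !is.na(ix)
  s <- panel$snps[ok, , drop = FALSE]
  fl <- mb$flipped[ix[ok]]
  data.frame(col = which(ok),
             snp_id = s$snp_id,
             cluster = mb$cluster[ix[ok]],
             cpos = canonical_position(s$position, fl, cm$L),
             pair = canonical_allele_pair(s$allele1, s$allele2, fl),
             flipped = fl,
             stringsAsFactors = FALSE)
}

#' Match SNPs inside shared clusters
#'
#' Two SNPs (one per pipeline, within the same shared cluster) match iff
#' their canonical-orientation positions are equal and their unordered allele
#' pairs (canonically complemented) are equal; each SNP matches at most one
#' partner.
#'
#' @param cm cluster_map from \code{\link{cluster_catalogs}}.
#' @param panelA6,panelB6 the two step-6 cascade outputs.
#' @return data.frame of matched pairs: cluster, canonical position, allele
#'   pair, source snp ids/columns and orientation flags for both sides.
#' @export
match_snps <- function(cm, panelA6, panelB6) {
  sa <- .canonical_snps(panelA6, cm, cm$pipelines[1])
  sb <- .canonical_snps(panelB6, cm, cm$pipelines[2])
  shared <- cm$clusters$cluster[cm$clusters$shared]
  sa <- sa[sa$cluster %in% shared & !is.na(sa$pair), ]
  sb <- sb[sb$cluster %in% shared & !is.na(sb$pair), ]
  sa$key <- paste(sa$cluster, sa$cpos, sa$pair)
  sb$key <- paste(sb$cluster, sb$cpos, sb$pair)
  sa <- sa[!duplicated(sa$key), ]
  sb <- sb[!duplicated(sb$key), ]
  ix <- match(sa$key, sb$key)
  hit <- !is.na(ix)
  out <- data.frame(cluster = sa$cluster[hit], cpos = sa$cpos[hit],
                    pair = sa$pair[hit],
                    snp_a = sa$snp_id[hit], col_a = sa$col[hit],
                    flip_a = sa$flipped[hit],
                    snp_b = sb$snp_id[ix[hit]], col_b = sb$col[ix[hit]],
                    flip_b = sb$flipped[ix[hit]],
                    stringsAsFactors = FALSE)
  out[order(out$cluster, out$cpos), ]
}

# Extract matched columns from a panel, complementing calls of flipped loci
# so both sides express genotypes in canonical orientation.
.canonical_calls <- function(panel, cols, flips) {
  calls <- panel$calls[, cols, drop = FALSE]
  if (any(flips)) calls[, flips] <- comp_calls(calls[, flips, drop = FALSE])
  calls
}

#' Build the COM (common) panel
#'
#' The COM SNP set is the matched-SNP set of the shared clusters; the first
#' SNP per cluster (smallest canonical position) is then retained, mirroring
#' the final cascade step. Genotypes are returned twice -- once under each
#' pipeline's calls, both expressed in canonical orientation -- because the
#' concordance analysis needs the same SNPs genotyped by both pipelines.
#'
#' @param cm cluster_map.
#' @param panelA6,panelB6 step-6 cascade outputs.
#' @return list with genotype matrices \code{A} and \code{B} (same SNP
#'   columns) and the match table \code{map}.
#' @export
build_com_panel <- function(cm, panelA6, panelB6) {
  mp <- match_snps(cm, panelA6, panelB6)
  first <- !duplicated(mp$cluster)        # mp is ordered by cluster, cpos
  mp <- mp[first, , drop = FALSE]
  com_ids <- sprintf("C%05d_p%02d", mp$cluster, mp$cpos)
  a1 <- substr(mp$pair, 1, 1); a2 <- substr(mp$pair, 3, 3)
  snps <- data.frame(snp_id = com_ids,
                     locus_id = sprintf("C%05d", mp$cluster),
                     position = mp$cpos, allele1 = a1, allele2 = a2,
                     stringsAsFactors = FALSE)
  mk <- function(panel, cols, flips, label) {
    calls <- .canonical_calls(panel, cols, flips)
    colnames(calls) <- com_ids
    update_observed_alleles(
      genotype_matrix(calls, panel$popmap, snps, label))
  }
  list(A = mk(panelA6, mp$col_a, mp$flip_a,
              paste0("COM/", cm$pipelines[1])),
       B = mk(panelB6, mp$col_b, mp$flip_b,
              paste0("COM/", cm$pipelines[2])),
       map = mp)
}

#' Build the MER (merged) panel
#'
#' MER is the COM panel plus the SNPs sitting on PRIVATE loci of each
#' pipeline (genotypes taken from their native pipeline, canonical
#' orientation), with one SNP per RAD locus retained throughout.
#'
#' @param cm cluster_map.
#' @param panelA6,panelB6 step-6 cascade outputs.
#' @param com result of \code{\link{build_com_panel}}; its \code{A}-side
#'   calls carry the COM part of MER.
#' @return genotype_matrix.
#' @export
build_mer_panel <- function(cm, panelA6, panelB6, com) {
  private <- cm$clusters$cluster[!cm$clusters$shared]
  pick_private <- function(panel, pipeline) {
    cs <- .canonical_snps(panel, cm, pipeline)
    cs <- cs[cs$cluster %in% private, , drop = FALSE]
    cs <- cs[order(cs$cluster, cs$cpos), , drop = FALSE]
    cs[!duplicated(cs$cluster), , drop = FALSE]   # first SNP per locus
  }
  pa <- pick_private(panelA6, cm$pipelines[1])
  pb <- pick_private(panelB6, cm$pipelines[2])
  core <- c("snp_id", "locus_id", "position", "allele1", "allele2")
  blocks <- list(com$A$calls)
  snps <- list(com$A$snps[core])
  grab <- function(panel, cs, label) {
    calls <- .canonical_calls(panel, cs$col, cs$flipped)
    ids <- sprintf("C%05d_p%02d", cs$cluster, cs$cpos)
    colnames(calls) <- ids
    a1 <- substr(cs$pair, 1, 1); a2 <- substr(cs$pair, 3, 3)
    list(calls = calls,
         snps = data.frame(snp_id = ids,
                           locus_id = sprintf("C%05d", cs$cluster),
                           position = cs$cpos, allele1 = a1, allele2 = a2,
                           stringsAsFactors = FALSE))
  }
  ga <- grab(panelA6, pa, cm$pipelines[1])
  gb <- grab(panelB6, pb, cm$pipelines[2])
  calls <- cbind(blocks[[1]], ga$calls, gb$calls)
  snps <- rbind(snps[[1]], ga$snps, gb$snps)
  ord <- order(snps$snp_id)
  update_observed_alleles(
    genotype_matrix(calls[, ord, drop = FALSE], com$A$popmap,
                    snps[ord, , drop = FALSE], "MER"))
}
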