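# Genotype-level comparison of two panels at matched SNPs: the seven
# mismatch categories (plus the concordant and both-missing cells needed for
# the conservation invariant) and attribution of missing-data mismatches to
# their mechanistic source.

CONCORDANCE_LEVELS <- c("ConcHom", "ConcHet", "BothMD",
                        "HomHom", "HomMD", "MDHom", "HetMD", "MDHet",
                        "HomHet", "HetHom")
MISMATCH_LEVELS <- CONCORDANCE_LEVELS[-(1:3)]

#' Classify a pair of genotype calls
#'
#' Category "X -> Y" means state X in the first panel and Y in the second
#' (panels are named left-to-right, e.g. STA then ALT). \code{HomHom} is the
#' discordant different-homozygote cell; identical states fall into the
#' concordant categories.
#'
#' @param callA,callB call strings (\code{"A/G"}-style, NA = missing);
#'   vectorised.
#' @return factor with levels ConcHom, ConcHet, BothMD, HomHom, HomMD,
#'   MDHom, HetMD, MDHet, HomHet, HetHom.
#' @export
classify_pair <- function(callA, callB) {
  stateA <- ifelse(is.na(callA), "MD", ifelse(is_het_call(callA), "Het", "Hom"))
  stateB <- ifelse(is.na(callB), "MD", ifelse(is_het_call(callB), "Het", "Hom"))
  out <- rep(NA_character_, length(stateA))
  out[stateA == "MD" & stateB == "MD"] <- "BothMD"
  same <- !is.na(callA) & !is.na(callB) & callA == callB
  out[same & stateA == "Hom"] <- "ConcHom"
  out[same & stateA == "Het"] <- "ConcHet"
  diff <- is.na(out)
  key <- paste0(stateA, stateB)
  map <- c(HomHom = "HomHom", HomMD = "HomMD", MDHom = "MDHom",
           HetMD = "HetMD", MDHet = "MDHet", HomHet = "HomHet",
           HetHom = "HetHom", HetHet = "HetHet")
  out[diff] <- map[key[diff]]
  # HetHet (two different heterozygotes) cannot occur at matched biallelic
  # SNPs -- both hets carry the same two alleles -- but the level is kept so
  # raw multi-allelic comparisons cannot silently misclassify.
  factor(out, levels = c(CONCORDANCE_LEVELS, "HetHet"))
}

#' Compare two panels at their matched SNPs
#'
#' Full cross-tabulation of \code{\link{classify_pair}} over every (sample,
#' SNP) cell, with frequencies relative to the total number of genotypes
#' (n_samples x n_SNPs).
#'
#' @param gmA,gmB genotype matrices with identical sample sets and identical
#'   SNP columns (e.g. the two sides of \code{\link{build_com_panel}}).
#' @return object of class \code{concordance_table}: data.frame of counts
#'   and frequencies per category plus totals.
#' @export
compare_panels <- function(gmA, gmB) {
  if (!identical(sort(rownames(gmA$calls)), sort(rownames(gmB$calls)))) {
    stop("sample sets differ between panels")
  }
  if (!identical(colnames(gmA$calls), colnames(gmB$calls))) {
    stop("panels must share the same matched SNP columns")
  }
  b <- gmB$calls[rownames(gmA$calls), , drop = FALSE]
  cls <- classify_pair(as.vector(gmA$calls), as.vector(b))
  counts <- table(cls)
  total <- length(cls)
  tab <- data.frame(category = names(counts), count = as.integer(counts),
                    frequency = if (total) as.numeric(counts) / total else 0,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, total_genotypes = total,
                 n_samples = nrow(gmA$calls), n_snps = ncol(gmA$calls),
                 panels = c(gmA$pipeline, gmB$pipeline)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("Concordance %s vs %s: %d genotypes (%d samples x %d SNPs)\n",
              x$panels[1], x$panels[2], x$total_genotypes, x$n_samples,
              x$n_snps))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

# Convenience: named count/frequency accessors.
concordance_counts <- function(ct) {
  stats::setNames(ct$table$count, ct$table$category)
}
concordance_freqs <- function(ct) {
  stats::setNames(ct$table$frequency, ct$table$category)
}

#' Attribute missing-data mismatches to their source
#'
#' Every cell where exactly one panel is missing is assigned to one of the
#' three de novo missing-data mechanisms, using the missing panel's depth at
#' that cell: (i) never genotyped -- total depth below the calling floor (or
#' the locus absent from that pipeline's catalogue); (ii) genotyped but
#' removed by the minimum-coverage filter (floor <= depth < filter);
#' (iii) enough coverage but an ambiguous/uncertain call (depth >= filter).
#'
#' @param gmA,gmB the two COM-side genotype matrices.
#' @param dmA,dmB the pipelines' depth matrices (native coordinates).
#' @param map match table from \code{\link{build_com_panel}} (columns
#'   \code{snp_a}, \code{snp_b} link COM columns to native depth columns).
#' @param call_floor caller depth floor (default 3).
#' @param cov_filter minimum-coverage filter threshold (default 8).
#' @return object of class \code{missing_source_table}: counts per
#'   (direction, source).
#' @export
attribute_missing <- function(gmA, gmB, dmA, dmB, map, call_floor = 3,
                              cov_filter = 8) {
  stopifnot(nrow(map) == ncol(gmA$calls))
  tdA <- total_depth(dmA)[rownames(gmA$calls), map$snp_a, drop = FALSE]
  tdB <- total_depth(dmB)[rownames(gmA$calls), map$snp_b, drop = FALSE]
  b <- gmB$calls[rownames(gmA$calls), , drop = FALSE]
  misA <- is.na(gmA$calls) & !is.na(b)
  misB <- is.na(b) & !is.na(gmA$calls)
  classify_depth <- function(d) {
    ifelse(is.na(d) | d < call_floor, "below_floor",
           ifelse(d < cov_filter, "coverage_filter", "uncertain_call"))
  }
  srcA <- classify_depth(tdA[misA])
  srcB <- classify_depth(tdB[misB])
  lv <- c("below_floor", "coverage_filter", "uncertain_call")
  tab <- rbind(
    data.frame(direction = sprintf("MD_in_%s", gmA$pipeline),
               source = lv,
               count = as.integer(table(factor(srcA, levels = lv))),
               stringsAsFactors = FALSE),
    data.frame(direction = sprintf("MD_in_%s", gmB$pipeline),
               source = lv,
               count = as.integer(table(factor(srcB, levels = lv))),
               stringsAsFactors = FALSE))
  structure(list(table = tab, call_floor = call_floor,
                 cov_filter = cov_filter,
                 total_md_mismatches = sum(tab$count)),
            class = "missing_source_table")
}

#' @export
print.missing_source_table <- function(x, ...) {
  cat(sprintf("Missing-genotype mismatch sources (floor %dx, filter %dx):\n",
              x$call_floor, x$cov_filter))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}
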