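#' Pairwise LD (r^2) between variants of a genotype panel
#'
#' r^2 is the squared Pearson correlation of dosages (equivalently, of
#' haplotype indicators when the panel holds phased haplotypes).
#'
#' @param geno \linkS4class{GenotypeMatrix} or variants x samples matrix.
#' @param a,b variant ids.
#' @export
ldR2 <- function(geno, a, b) {
  d <- if (methods::is(geno, "GenotypeMatrix")) dosages(geno) else geno
  cor(d[a, ], d[b, ])^2
}

#' Expand sentinel SNPs with LD proxies
#'
#' A proxy has r^2 strictly above \code{r2_min} with the sentinel, lies on
#' the same chromosome within \code{window} bp; each sentinel is a member of
#' its own proxy set. Expansion is idempotent on the returned union.
#'
#' @param geno \linkS4class{GenotypeMatrix} providing dosages and positions.
#' @param snps sentinel variant ids.
#' @param r2_min proxy threshold (strict; default 0.8).
#' @param window search window in bp (default 1 Mb).
#' @return named list, sentinel -> character vector of proxies (incl. self).
#' @export
expandProxies <- function(geno, snps, r2_min = 0.8, window = 1e6) {
  d <- dosages(geno)
  v <- variantInfo(geno)
  out <- lapply(snps, function(s) {
    i <- match(s, v$id)
    if (is.na(i)) return(s)
    cand <- which(v$chrom == v$chrom[i] & abs(v$pos - v$pos[i]) <= window)
    cand <- cand[apply(d[cand, , drop = FALSE], 1, var) > 0]
    if (var(d[i, ]) == 0) return(s)
    r2 <- drop(cor(d[i, ], t(d[cand, , drop = FALSE])))^2
    union(s, v$id[cand[r2 > r2_min]])
  })
  names(out) <- snps
  out
}

#' Overlap GWAS SNPs (plus proxies) with eSNP sets
#'
#' A GWAS SNP overlaps iff itself or any of its proxies is a member of the
#' target set.
#'
#' @param gwas_snps sentinel GWAS variant ids.
#' @param proxies named list from [expandProxies()] (sentinel -> proxy set).
#' @param esnp_set character set of eSNPs.
#' @param best_esnp_set optional set of best eSNPs for a second overlap.
#' @return list: per-sentinel logical \code{hits}, counts, and the matched
#'   pair list (sentinel, matching esnp).
#' @export
overlapGwasEsnps <- function(gwas_snps, proxies, esnp_set,
                             best_esnp_set = NULL) {
  hit_of <- function(s, target) {
    px <- if (s %in% names(proxies)) proxies[[s]] else s
    intersect(px, target)
  }
  matches <- lapply(gwas_snps, hit_of, target = esnp_set)
  hits <- lengths(matches) > 0
  pairs <- data.frame(
    gwas_snp = rep(gwas_snps, lengths(matches)),
    esnp = unlist(matches), stringsAsFactors = FALSE, row.names = NULL)
  out <- list(hits = setNames(hits, gwas_snps),
              n = length(gwas_snps), n_overlap = sum(hits),
              pairs = pairs)
  if (!is.null(best_esnp_set)) {
    bhits <- lengths(lapply(gwas_snps, hit_of,
                            target = best_esnp_set)) > 0
    out$n_overlap_best <- sum(bhits)
    out$hits_best <- setNames(bhits, gwas_snps)
  }
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Conditional on the margins: the p-value sums the hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @param a,b,c,d table cells (first row a,b; second row c,d).
#' @return list(odds_ratio, p).
#' @examples
#' fisherExact2x2(75, 230, 3711, 16209)  # ~0.0096
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  ft <- fisher.test(matrix(c(a, c, b, d), 2, 2))
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Draw matched random SNP sets
#'
#' Each returned set has the cardinality of the input and matches it SNP by
#' SNP on minor allele frequency (within \code{maf_tol} relative deviation)
#' and on LD-buddy count, gene density and distance to the nearest gene
#' (within \code{other_tol}); no input SNP appears in any set; sampling is
#' without replacement within a set. Input SNPs with no eligible match are
#' skipped with a warning.
#'
#' @param input_snps ids of the input SNPs (must appear in
#'   \code{universe$snp}).
#' @param universe data.frame (snp, maf, ld_buddies, gene_density,
#'   dist_nearest_gene) covering inputs and candidates.
#' @param n_sets number of matched sets (default 100).
#' @param maf_tol,other_tol relative tolerances (default 0.10, 0.50).
#' @param seed RNG seed.
#' @return list: \code{sets} (list of character vectors), \code{n_skipped}.
#' @export
matchedSnpSets <- function(input_snps, universe, n_sets = 100L,
                           maf_tol = 0.10, other_tol = 0.50, seed = 1L) {
  set.seed(seed)
  rownames(universe) <- universe$snp
  cand_pool <- universe[!universe$snp %in% input_snps, , drop = FALSE]
  rel_ok <- function(x, x0, tol)
    if (x0 == 0) x == 0 else abs(x - x0) / abs(x0) <= tol
  eligible <- lapply(input_snps, function(s) {
    u0 <- universe[s, ]
    ok <- vapply(seq_len(nrow(cand_pool)), function(i) {
      u <- cand_pool[i, ]
      rel_ok(u$maf, u0$maf, maf_tol) &&
        rel_ok(u$ld_buddies, u0$ld_buddies, other_tol) &&
        rel_ok(u$gene_density, u0$gene_density, other_tol) &&
        rel_ok(u$dist_nearest_gene, u0$dist_nearest_gene, other_tol)
    }, logical(1))
    cand_pool$snp[ok]
  })
  names(eligible) <- input_snps
  skipped <- lengths(eligible) == 0
  if (any(skipped))
    warning(sum(skipped), " input SNPs had no eligible match and were ",
            "skipped")
  eligible <- eligible[!skipped]
  sets <- lapply(seq_len(n_sets), function(k) {
    chosen <- character(0)
    for (s in names(eligible)) {
      avail <- setdiff(eligible[[s]], chosen)
      if (!length(avail)) avail <- eligible[[s]]  # fallback: allow reuse
      chosen <- c(chosen, avail[sample.int(length(avail), 1L)])
    }
    chosen
  })
  list(sets = sets, n_skipped = sum(skipped))
}

#' Enrichment of an overlap against matched null sets
#'
#' Fold = observed count / mean count across the matched sets. The p-value
#' comes from Fisher's exact test on the pooled 2x2 table (input hits vs
#' misses against pooled matched-set hits vs misses); an empirical rank
#' p-value over the null counts is available as an option.
#'
#' @param observed_overlap observed hit count of the input set.
#' @param n_input input set cardinality.
#' @param null_counts per-matched-set hit counts.
#' @param n_per_set matched set cardinality (defaults to \code{n_input}).
#' @param method \code{"pooled_fisher"} (default) or \code{"empirical"}.
#' @return list(fold, p, observed, expected).
#' @export
enrichmentTest <- function(observed_overlap, n_input, null_counts,
                           n_per_set = n_input,
                           method = c("pooled_fisher", "empirical")) {
  method <- match.arg(method)
  expected <- mean(null_counts)
  if (expected == 0 && observed_overlap > 0) {
    warning("all matched-set counts are zero; fold guarded by epsilon")
    fold <- observed_overlap / max(expected, .Machine$double.eps)
  } else fold <- observed_overlap / expected
  p <- if (method == "pooled_fisher")
    fisherExact2x2(observed_overlap, n_input - observed_overlap,
                   sum(null_counts),
                   length(null_counts) * n_per_set - sum(null_counts))$p
  else (1 + sum(null_counts >= observed_overlap)) /
    (length(null_counts) + 1)
  list(fold = fold, p = p, observed = observed_overlap,
       expected = expected)
}

#' Read a BED annotation track
#'
#' BED is 0-based half-open; the returned GRanges is 1-based inclusive
#' (the conversion is done here, once).
#'
#' @param path BED file (chrom, start, end, optional name).
#' @param label track label used when the name column is absent.
#' @return GRanges with a \code{label} metadata column.
#' @export
readBedTrack <- function(path, label = basename(path)) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    bed[[1]], IRanges::IRanges(bed[[2]] + 1L, bed[[3]]))
  gr$label <- if (ncol(bed) >= 4) as.character(bed[[4]]) else label
  gr
}

#' Annotate SNPs against interval tracks
#'
#' A SNP at 1-based position p hits a BED interval \[s, e) iff
#' s <= p-1 < e; labels from multiple tracks are unioned per SNP.
#'
#' @param snps data.frame (id, chrom, pos) or
#'   \linkS4class{GenotypeMatrix}.
#' @param tracks a GRanges with a \code{label} column (see
#'   [readBedTrack()]) or a list of them.
#' @return named list, snp id -> character vector of labels (possibly
#'   empty).
#' @export
annotateSnps <- function(snps, tracks) {
  if (methods::is(snps, "GenotypeMatrix")) snps <- variantInfo(snps)
  if (!is.list(tracks)) tracks <- list(tracks)
  gr_s <- GenomicRanges::GRanges(snps$chrom,
                                 IRanges::IRanges(snps$pos, snps$pos))
  out <- setNames(vector("list", nrow(snps)), snps$id)
  out[] <- list(character(0))
  for (tr in tracks) {
    hits <- GenomicRanges::findOverlaps(gr_s, tr)
    qi <- S4Vectors::queryHits(hits)
    lab <- tr$label[S4Vectors::subjectHits(hits)]
    for (k in seq_along(qi))
      out[[qi[k]]] <- union(out[[qi[k]]], lab[k])
  }
  out
}
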