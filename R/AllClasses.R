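#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats approx coef cor dhyper lm lm.fit mad median na.omit
#'   p.adjust pchisq pnorm prcomp pt qnorm quantile resid rbinom rnorm runif
#'   sd setNames smooth.spline var weighted.mean complete.cases ks.test
#'   fisher.test predict
#' @importFrom utils head modifyList packageVersion
NULL

#' GenotypeMatrix: per-sample dosages with variant metadata
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a
#' variants-by-samples dosage assay (values in \[0, 2\]) together with variant
#' metadata (\code{chrom}, \code{pos} 1-based, \code{ref}, \code{alt},
#' optional imputation \code{impR2}) in \code{rowData} and per-sample
#' covariates in \code{colData}.
#'
#' @slot .. inherits all slots from SummarizedExperiment; the single assay is
#'   named \code{"dosage"}.
#' @seealso [GenotypeMatrix()] constructor, [dosages()], [variantInfo()],
#'   [sampleInfo()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (any(!is.na(d) & (d < 0 | d > 2)))
      msg <- c(msg, "dosages must lie in [0, 2]")
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("chrom", "pos")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
  # duplicated (chrom, pos) entries are tolerated here: raw pre-QC panels
  # contain them and filterVariants() is the stage that removes them
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' ExpressionMatrix: genes-by-samples expression with coordinates and a
#' normalisation stage tag
#'
#' Extension of \linkS4class{SummarizedExperiment}. \code{rowData} carries
#' gene coordinates (\code{chrom}, \code{start}, \code{end}, 1-based
#' inclusive); \code{colData} carries sample covariates including an optional
#' \code{batch} label. The metadata field \code{stage} tracks the position in
#' the normalisation chain and may only move forward through
#' \code{tpm -> log -> qnorm -> rbint}.
#'
#' @seealso [ExpressionMatrix()], [exprValues()], [geneInfo()], [exprStage()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

.expr_stages <- c("tpm", "log", "qnorm", "rbint")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  st <- S4Vectors::metadata(object)$stage
  if (is.null(st) || !st %in% .expr_stages)
    msg <- c(msg, "metadata()$stage must be one of tpm/log/qnorm/rbint")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "start", "end") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain chrom/start/end gene coordinates")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  if (length(msg)) msg else TRUE
})

#' MrInstrumentSet: harmonised per-instrument summary statistics
#'
#' Holds, per instrument SNP, the exposure association (\code{beta_x},
#' \code{se_x}; SD expression per allele) and the outcome association
#' (\code{beta_y}, \code{se_y}; trait units per allele), aligned to a common
#' effect allele.
#'
#' @slot instruments data.frame with columns snp, effect_allele, beta_x,
#'   se_x, beta_y, se_y (optional eaf).
#' @slot dropped data.frame of instruments removed during harmonisation with
#'   a reason column.
#' @export
setClass("MrInstrumentSet",
         representation(instruments = "data.frame", dropped = "data.frame"),
         prototype(dropped = data.frame(snp = character(),
                                        reason = character())))

setValidity("MrInstrumentSet", function(object) {
  ins <- object@instruments
  need <- c("snp", "beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% colnames(ins)))
    return(paste("instruments need columns:", paste(need, collapse = ", ")))
  if (nrow(ins)) {
    if (any(ins$beta_x == 0)) return("beta_x must be nonzero after selection")
    if (any(ins$se_x <= 0) || any(ins$se_y <= 0)) return("ses must be > 0")
    if (anyDuplicated(ins$snp)) return("duplicate instrument snp ids")
  }
  TRUE
})

#' PermutationCalibration: per-gene empirical null of the smallest meta-P
#'
#' Stores, for each gene, the B smallest permuted meta-P values (the empirical
#' cdf F_i), the observed smallest meta-P, the permutation-adjusted P, the
#' Storey q-value, the genome-wide threshold P_t and the per-gene nominal
#' threshold P_t,i.
#'
#' @slot null matrix genes x B of permuted minimum meta-P values.
#' @slot observed named numeric, observed minimum meta-P per gene.
#' @slot adjusted named numeric, permutation-adjusted P per gene.
#' @slot qvalue named numeric, Storey q-values of the adjusted P.
#' @slot pt numeric(1), genome-wide adjusted-P threshold.
#' @slot pt_gene named numeric, per-gene nominal threshold P_t,i.
#' @slot B integer(1), number of permutations.
#' @export
setClass("PermutationCalibration",
         representation(null = "matrix", observed = "numeric",
                        adjusted = "numeric", qvalue = "numeric",
                        pt = "numeric", pt_gene = "numeric", B = "integer"))

setValidity("PermutationCalibration", function(object) {
  msg <- character()
  if (nrow(object@null) != length(object@observed))
    msg <- c(msg, "null matrix rows must match observed length")
  if (length(object@adjusted) &&
      (any(object@adjusted <= 0) || any(object@adjusted > 1)))
    msg <- c(msg, "adjusted p must lie in (0, 1]")
  if (length(object@B) && object@B[1] != ncol(object@null))
    msg <- c(msg, "B must equal ncol(null)")
  if (length(msg)) msg else TRUE
})
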