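#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix, variants x samples, values in \[0, 2\].
#' @param variants data.frame with one row per variant: \code{id},
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt}, optionally
#'   \code{impR2} (imputation quality).
#' @param samples data.frame of per-sample covariates (rownames or an
#'   \code{id} column giving sample ids). May be NULL.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' d <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("v1", "v2"), c("s1", "s2")))
#' v <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
#'                 ref = "A", alt = "G")
#' GenotypeMatrix(d, v)
#' @export
GenotypeMatrix <- function(dosages, variants, samples = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages))) rownames(dosages) <- variants$id
  if (is.null(samples)) {
    sid <- colnames(dosages)
    if (is.null(sid)) sid <- paste0("S", seq_len(ncol(dosages)))
    samples <- S4Vectors::DataFrame(row.names = sid)
  } else {
    samples <- S4Vectors::DataFrame(samples)
    if (is.null(rownames(samples)) && "id" %in% colnames(samples))
      rownames(samples) <- samples$id
  }
  colnames(dosages) <- rownames(samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages),
    rowData = S4Vectors::DataFrame(variants, row.names = variants$id),
    colData = samples)
  methods::new("GenotypeMatrix", se)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples.
#' @param genes data.frame with \code{id}, \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive gene body coordinates).
#' @param samples data.frame of per-sample covariates (may include
#'   \code{batch}); NULL for none.
#' @param stage normalisation stage tag, one of
#'   \code{"tpm"}, \code{"log"}, \code{"qnorm"}, \code{"rbint"}.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, genes, samples = NULL, stage = "tpm") {
  stage <- match.arg(stage, .expr_stages)
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- genes$id
  if (is.null(samples)) {
    sid <- colnames(values)
    if (is.null(sid)) sid <- paste0("S", seq_len(ncol(values)))
    samples <- S4Vectors::DataFrame(row.names = sid)
  } else {
    samples <- S4Vectors::DataFrame(samples)
    if (is.null(rownames(samples)) && "id" %in% colnames(samples))
      rownames(samples) <- samples$id
  }
  colnames(values) <- rownames(samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(values), stage),
    rowData = S4Vectors::DataFrame(genes, row.names = genes$id),
    colData = samples)
  S4Vectors::metadata(se)$stage <- stage
  methods::new("ExpressionMatrix", se)
}

#' @rdname GenotypeMatrix
#' @param x a GenotypeMatrix
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @rdname GenotypeMatrix
#' @export
variantInfo <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' Per-sample covariate table of a container
#' @param x a GenotypeMatrix or ExpressionMatrix
#' @export
sampleInfo <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @rdname ExpressionMatrix
#' @param x an ExpressionMatrix
#' @export
exprValues <- function(x)
  SummarizedExperiment::assay(x, exprStage(x))

#' @rdname ExpressionMatrix
#' @export
geneInfo <- function(x)
  as.data.frame(SummarizedExperiment::rowData(x))

#' @rdname ExpressionMatrix
#' @export
exprStage <- function(x) S4Vectors::metadata(x)$stage

# internal: return a copy of x at a later normalisation stage
.setStage <- function(x, values, stage) {
  stopifnot(match(stage, .expr_stages) >= match(exprStage(x), .expr_stages))
  SummarizedExperiment::assays(x, withDimnames = FALSE) <-
    stats::setNames(list(values), stage)
  S4Vectors::metadata(x)$stage <- stage
  methods::validObject(x)
  x
}

#' @rdname MrInstrumentSet-class
#' @param instruments data.frame with columns snp, effect_allele, beta_x,
#'   se_x, beta_y, se_y
#' @param dropped data.frame of harmonisation casualties (snp, reason)
#' @export
MrInstrumentSet <- function(instruments,
                            dropped = data.frame(snp = character(),
                                                 reason = character())) {
  methods::new("MrInstrumentSet",
               instruments = as.data.frame(instruments),
               dropped = as.data.frame(dropped))
}

#' @rdname MrInstrumentSet-class
#' @param x an MrInstrumentSet
#' @export
instruments <- function(x) x@instruments

#' Number of instruments
#' @param x an MrInstrumentSet
#' @export
setMethod("length", "MrInstrumentSet", function(x) nrow(x@instruments))

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d variants x %d samples\n",
              nrow(object), ncol(object)))
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(rd$chrom), collapse = ", ")))
  methods::callNextMethod()
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix [stage=%s]: %d genes x %d samples\n",
              exprStage(object), nrow(object), ncol(object)))
  methods::callNextMethod()
})

setMethod("show", "MrInstrumentSet", function(object) {
  cat(sprintf("MrInstrumentSet: %d instruments (%d dropped)\n",
              nrow(object@instruments), nrow(object@dropped)))
  if (nrow(object@instruments))
    print(utils::head(object@instruments, 5))
})

setMethod("show", "PermutationCalibration", function(object) {
  cat(sprintf(
    "PermutationCalibration: %d genes, B=%d permutations, P_t=%.3g\n",
    nrow(object@null), object@B, object@pt))
})

#' Accessors for PermutationCalibration
#'
#' @param x a \linkS4class{PermutationCalibration}
#' @return \code{nullMinP}: the genes x B matrix of permuted minimum meta-P;
#'   \code{adjustedP}/\code{geneQvalues}: named vectors;
#'   \code{genomewideThresholdValue}: P_t; \code{perGeneThresholds}: P_t,i.
#' @export
nullMinP <- function(x) x@null
#' @rdname nullMinP
#' @export
adjustedP <- function(x) x@adjusted
#' @rdname nullMinP
#' @export
geneQvalues <- function(x) x@qvalue
#' @rdname nullMinP
#' @export
genomewideThresholdValue <- function(x) x@pt
#' @rdname nullMinP
#' @export
perGeneThresholds <- function(x) x@pt_gene
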