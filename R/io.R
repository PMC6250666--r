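# TSV interchange dialect: tab-delimited, header row, UTF-8, '.' for
# missing values. All 1-based <-> 0-based coordinate conversions are done in
# this file only (BED handling sits in readBedTrack()).

.write_tsv <- function(d, path) {
  data.table::fwrite(d, path, sep = "\t", na = ".", quote = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", na.strings = ".",
                                  header = TRUE))
}

#' Write / read a GenotypeMatrix as dosage + variant metadata TSVs
#'
#' The dosage table is variants x samples with an \code{id} key column; the
#' variant table carries chrom, pos (1-based), ref, alt and any extra
#' columns.
#'
#' @param geno a \linkS4class{GenotypeMatrix}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return (write) the two paths, invisibly; (read) a GenotypeMatrix.
#' @export
writeGenotypeTsv <- function(geno, dir, prefix = "genotypes") {
  d <- cbind(data.frame(id = rownames(geno)), as.data.frame(dosages(geno)))
  p1 <- .write_tsv(d, file.path(dir, paste0(prefix, "_dosage.tsv")))
  p2 <- .write_tsv(variantInfo(geno),
                   file.path(dir, paste0(prefix, "_variants.tsv")))
  p3 <- .write_tsv(cbind(data.frame(id = colnames(geno)),
                         sampleInfo(geno)[setdiff(colnames(sampleInfo(geno)),
                                                  "id")]),
                   file.path(dir, paste0(prefix, "_samples.tsv")))
  invisible(c(p1, p2, p3))
}

#' @rdname writeGenotypeTsv
#' @export
readGenotypeTsv <- function(dir, prefix = "genotypes") {
  d <- .read_tsv(file.path(dir, paste0(prefix, "_dosage.tsv")))
  v <- .read_tsv(file.path(dir, paste0(prefix, "_variants.tsv")))
  s <- .read_tsv(file.path(dir, paste0(prefix, "_samples.tsv")))
  dm <- as.matrix(d[-1]); rownames(dm) <- d$id
  v$chrom <- as.character(v$chrom)
  GenotypeMatrix(dm, v, s)
}

#' Write / read an ExpressionMatrix as expression + gene annotation TSVs
#'
#' Gene coordinates are 1-based inclusive.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param dir directory.
#' @param prefix file-name prefix.
#' @export
writeExpressionTsv <- function(expr, dir, prefix = "expression") {
  d <- cbind(data.frame(id = rownames(expr)),
             as.data.frame(exprValues(expr)))
  p1 <- .write_tsv(d, file.path(dir, paste0(prefix, "_values.tsv")))
  p2 <- .write_tsv(geneInfo(expr),
                   file.path(dir, paste0(prefix, "_genes.tsv")))
  invisible(c(p1, p2, stage = exprStage(expr)))
}

#' @rdname writeExpressionTsv
#' @param stage stage tag of the stored values.
#' @export
readExpressionTsv <- function(dir, prefix = "expression", stage = "tpm") {
  d <- .read_tsv(file.path(dir, paste0(prefix, "_values.tsv")))
  g <- .read_tsv(file.path(dir, paste0(prefix, "_genes.tsv")))
  vm <- as.matrix(d[-1]); rownames(vm) <- d$id
  g$chrom <- as.character(g$chrom)
  ExpressionMatrix(vm, g, stage = stage)
}

#' Read a GWAS summary statistics TSV
#'
#' Expected columns: snp, effect_allele, other_allele, beta, se, p
#' (optionally chrom, pos, n).
#' @param path TSV path.
#' @export
readGwasTsv <- function(path) {
  d <- .read_tsv(path)
  need <- c("snp", "effect_allele", "beta", "se", "p")
  if (!all(need %in% colnames(d)))
    stop("GWAS summary file needs columns: ", paste(need, collapse = ", "))
  d
}

#' Write ground truth as JSON
#' @param truth a GroundTruth list.
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  keep <- truth[c("planted_pairs", "trait_model", "mr_truth")]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read / write a run configuration YAML
#'
#' Unknown keys are rejected; the parsed config round-trips bit-identically
#' through [writeRunConfig()].
#'
#' @param path YAML path.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, raw)
  # yaml maps come back as lists; restore the named-numeric convention
  if (!is.null(cfg$sim$covariate_effects))
    cfg$sim$covariate_effects <- unlist(cfg$sim$covariate_effects)
  if (!is.null(cfg$sim$maf_range))
    cfg$sim$maf_range <- unlist(cfg$sim$maf_range)
  cfg
}

#' @rdname readRunConfig
#' @param config a run configuration list.
#' @export
writeRunConfig <- function(config, path) {
  # yaml drops the names of named atomic vectors; store them as maps
  if (!is.null(config$sim$covariate_effects))
    config$sim$covariate_effects <- as.list(config$sim$covariate_effects)
  yaml::write_yaml(config, path)
  invisible(path)
}
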