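#' Marker read-count table
#'
#' Container for biallelic SNP read counts: per marker (rows) and sample
#' (columns) reference and alternative allele depths, plus marker metadata
#' (chromosome, position, annotation class). A cell is missing when its total
#' depth is zero.
#'
#' @param markers data.frame with columns `chrom`, `pos`, `id` and optionally
#'   `annotation` (one of `"nonsynonymous"`, `"synonymous"`, `"noncoding"`,
#'   `"unannotated"`). Positions must be strictly increasing within chromosome.
#' @param samples character vector of clone ids.
#' @param ref_depth,alt_depth integer matrices (markers x samples) of
#'   non-negative read depths; `NA` is treated as depth 0.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(markers, samples, ref_depth, alt_depth) {
  markers <- as.data.frame(markers)
  stopifnot(all(c("chrom", "pos", "id") %in% names(markers)))
  if (is.null(markers$annotation)) markers$annotation <- "unannotated"
  markers$chrom <- as.character(markers$chrom)
  samples <- as.character(samples)
  ref_depth <- as.matrix(ref_depth)
  alt_depth <- as.matrix(alt_depth)
  ref_depth[is.na(ref_depth)] <- 0L
  alt_depth[is.na(alt_depth)] <- 0L
  storage.mode(ref_depth) <- "integer"
  storage.mode(alt_depth) <- "integer"
  if (any(ref_depth < 0) || any(alt_depth < 0))
    stop("read depths must be non-negative")
  if (nrow(ref_depth) != nrow(markers) || ncol(ref_depth) != length(samples) ||
      !all(dim(ref_depth) == dim(alt_depth)))
    stop("depth matrix dimensions must be markers x samples")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  dimnames(ref_depth) <- dimnames(alt_depth) <- list(markers$id, samples)
  structure(
    list(markers = markers, samples = samples,
         ref_depth = ref_depth, alt_depth = alt_depth),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$markers), "markers x", length(x$samples),
      "samples on", length(unique(x$markers$chrom)), "chromosome(s)\n")
  cat("annotation:",
      paste(names(table(x$markers$annotation)),
            table(x$markers$annotation), collapse = ", "), "\n")
  invisible(x)
}

n_markers <- function(x) nrow(x$markers)
n_samples <- function(x) length(x$samples)

total_depth <- function(x) x$ref_depth + x$alt_depth

#' Subset a variant table
#'
#' @param x variant_table.
#' @param markers logical/integer index over markers, or marker ids.
#' @param samples logical/integer index over samples, or sample ids.
#' @return variant_table restricted to the selection, order preserved.
#' @export
subset_variants <- function(x, markers = NULL, samples = NULL) {
  mi <- seq_len(n_markers(x))
  si <- seq_len(n_samples(x))
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, x$markers$id) else mi[markers]
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, x$samples) else si[samples]
  }
  variant_table(x$markers[mi, , drop = FALSE], x$samples[si],
                x$ref_depth[mi, si, drop = FALSE],
                x$alt_depth[mi, si, drop = FALSE])
}

#' Read a variant table from VCF
#'
#' Expects a biallelic VCF with an `AD` FORMAT field (ref,alt depths). An
#' optional `ANN=` INFO entry carries the annotation class.
#'
#' @param path VCF file (plain text or gzipped).
#' @return variant_table.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  ref <- apply(ad, 2, function(col)
    suppressWarnings(as.integer(vapply(strsplit(col, ","), `[`, "", 1L))))
  alt <- apply(ad, 2, function(col)
    suppressWarnings(as.integer(vapply(strsplit(col, ","), function(z)
      if (length(z) >= 2) z[2] else NA_character_, ""))))
  ann <- vcfR::extract.info(v, element = "ANN")
  if (is.null(ann) || all(is.na(ann))) ann <- "unannotated"
  ids <- fix[, "ID"]
  miss_id <- is.na(ids) | ids == "."
  ids[miss_id] <- paste0(fix[miss_id, "CHROM"], "_", fix[miss_id, "POS"])
  variant_table(
    markers = data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = ids,
                         annotation = ifelse(is.na(ann), "unannotated", ann)),
    samples = colnames(ad),
    ref_depth = matrix(ref, nrow = nrow(fix)),
    alt_depth = matrix(alt, nrow = nrow(fix)))
}

#' Write a variant table as minimal VCF
#'
#' Emits CHROM, POS, ID, REF/ALT placeholders, an `ANN=` INFO tag with the
#' annotation class, and `AD:DP` genotype fields. Coordinates are 1-based.
#'
#' @param x variant_table.
#' @param path output file.
#' @export
write_variant_vcf <- function(x, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=ANN,Number=1,Type=String,Description="Annotation class">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  dp <- total_depth(x)
  gt <- matrix(paste0(x$ref_depth, ",", x$alt_depth, ":", dp),
               nrow = n_markers(x))
  body <- apply(cbind(x$markers$chrom, x$markers$pos, x$markers$id, "A", "T",
                      ".", "PASS", paste0("ANN=", x$markers$annotation),
                      "AD:DP", gt),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
}

#' Read/write a variant table as TSV
#'
#' Long-format TSV with columns marker, chrom, pos, annotation, sample,
#' ref_depth, alt_depth.
#'
#' @param x variant_table (for writing).
#' @param path file path.
#' @export
write_variant_tsv <- function(x, path) {
  long <- data.frame(
    marker = rep(x$markers$id, times = n_samples(x)),
    chrom = rep(x$markers$chrom, times = n_samples(x)),
    pos = rep(x$markers$pos, times = n_samples(x)),
    annotation = rep(x$markers$annotation, times = n_samples(x)),
    sample = rep(x$samples, each = n_markers(x)),
    ref_depth = as.vector(x$ref_depth),
    alt_depth = as.vector(x$alt_depth))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_variant_tsv
#' @export
read_variant_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  mk <- unique(long[, c("marker", "chrom", "pos", "annotation")])
  samples <- unique(long$sample)
  mi <- match(long$marker, mk$marker)
  si <- match(long$sample, samples)
  ref <- alt <- matrix(0L, nrow(mk), length(samples))
  ref[cbind(mi, si)] <- long$ref_depth
  alt[cbind(mi, si)] <- long$alt_depth
  variant_table(data.frame(chrom = mk$chrom, pos = mk$pos, id = mk$marker,
                           annotation = mk$annotation),
                samples, ref, alt)
}
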