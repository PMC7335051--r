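#' Genotype matrix container
#'
#' Individuals x biallelic variants, coded as the number of alternate alleles
#' (0/1/2, `NA` for missing), plus a variant record table.
#'
#' @param ids character vector of individual ids.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`.
#' @param codes numeric matrix `length(ids)` x `nrow(variants)` with entries
#'   in {0, 1, 2, NA}.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(ids, variants, codes) {
  codes <- as.matrix(codes)
  if (nrow(codes) != length(ids) || ncol(codes) != nrow(variants))
    stop("genotype_matrix: dimension mismatch")
  ok <- codes %in% c(0, 1, 2) | is.na(codes)
  if (!all(ok)) stop("genotype_matrix: codes must be 0/1/2/NA")
  if (any(variants$pos <= 0)) stop("genotype_matrix: positions must be positive")
  rownames(codes) <- ids
  colnames(codes) <- variants$id
  structure(list(ids = as.character(ids), variants = variants, codes = codes),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%.1f%% missing)\n",
              length(x$ids), nrow(x$variants), 100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  genotype_matrix(x$ids[i], x$variants[j, , drop = FALSE],
                  x$codes[i, j, drop = FALSE])
}

#' Write genotypes as VCF v4.2
#'
#' Minimal unphased GT-only emitter matching the VCF v4.2 text layout.
#'
#' @param G `genotype_matrix`
#' @param path output file
#' @export
write_vcf <- function(G, path) {
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(G$variants)), function(j) {
    v <- G$variants[j, ]
    calls <- ifelse(is.na(G$codes[, j]), "./.", gt[G$codes[, j] + 1])
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$ids), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Uses `vcfR` for parsing; keeps biallelic SNP records and counts alternate
#' alleles from the GT field (phased or unphased).
#'
#' @param path VCF file (plain or gzip).
#' @return `genotype_matrix`
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  codes <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(colnames(gt), variants, t(codes))
}

#' Write / read genotypes in PED/MAP text format
#'
#' `write_pedmap` emits `<prefix>.ped` (family, individual, father, mother,
#' sex, phenotype, then two allele columns per variant) and `<prefix>.map`
#' (chrom, id, genetic distance 0, position).
#'
#' @param G `genotype_matrix`
#' @param prefix file prefix
#' @return `read_pedmap` returns a `genotype_matrix`.
#' @export
write_pedmap <- function(G, prefix) {
  map <- data.frame(G$variants$chrom, G$variants$id, 0, G$variants$pos)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  ped_geno <- lapply(seq_len(nrow(G$variants)), function(j) {
    a <- G$variants$ref[j]; b <- G$variants$alt[j]
    al <- rbind(c(a, a), c(a, b), c(b, b))
    out <- matrix("0", length(G$ids), 2)
    known <- !is.na(G$codes[, j])
    out[known, ] <- al[G$codes[known, j] + 1, , drop = FALSE]
    out
  })
  ped <- cbind(G$ids, G$ids, 0, 0, 0, -9, do.call(cbind, ped_geno))
  utils::write.table(ped, paste0(prefix, ".ped"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_pedmap
#' @export
read_pedmap <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos"),
                           colClasses = c("character", "character", "numeric", "integer"))
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                           colClasses = "character")
  ids <- ped[[2]]
  geno_cols <- ped[, -(1:6), drop = FALSE]
  p <- nrow(map)
  codes <- matrix(NA_real_, length(ids), p)
  ref <- alt <- character(p)
  for (j in seq_len(p)) {
    a1 <- geno_cols[[2 * j - 1]]; a2 <- geno_cols[[2 * j]]
    alleles <- setdiff(unique(c(a1, a2)), "0")
    # first-seen allele is REF; a monomorphic variant has no ALT observed
    ref[j] <- if (length(alleles)) alleles[1] else "N"
    alt[j] <- if (length(alleles) > 1) alleles[2] else "."
    known <- a1 != "0" & a2 != "0"
    codes[known, j] <- (a1[known] == alt[j]) + (a2[known] == alt[j])
  }
  variants <- data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(ids, variants, codes)
}
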