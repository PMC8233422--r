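# Readers and writers for the pipeline's exchange formats: pedigree CSV,
# PLINK RAW/MAP dosage text, phenotype CSV, GFF3/BED gene models (through
# rtracklayer, normalised to the internal 1-based closed convention), GMT
# gene sets, and coordinate-list text for sparse symmetric matrices.
# Round-trips (read of a write) are identities; malformed lines raise
# line-numbered errors.

#' @rdname read_write
#' @name read_write
#' @title Read and write pipeline exchange formats
#' @description Plain-text readers/writers for every structure the pipeline
#'   exchanges. `0` encodes an unknown parent in pedigrees; `NA` encodes a
#'   missing genotype call in PLINK RAW.
#' @param pedigree,genotypes,snp_map,phenotypes,genes,sets,m Objects to write.
#' @param path File path.
#' @return Readers return the corresponding in-memory structure; writers
#'   return `path` invisibly.
NULL

#' @rdname read_write
#' @export
write_pedigree <- function(pedigree, path) {
  write.table(pedigree[, c("animal", "sire", "dam")], path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_write
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = ",",
                    colClasses = "integer")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    data_error("%s: expected header animal,sire,dam", path)
  bad <- which(!complete.cases(ped))
  if (length(bad))
    data_error("%s: malformed pedigree record at line %d", path, bad[1] + 1L)
  ped
}

#' @rdname read_write
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = ",", row.names = FALSE, quote = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname read_write
#' @export
read_phenotypes <- function(path) {
  ph <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                   na.strings = "NA")
  if (!"y" %in% names(ph)) data_error("%s: phenotype file lacks a 'y' column", path)
  bad <- which(!ph$y %in% c(0L, 1L) & !is.na(ph$y))
  if (length(bad))
    data_error("%s: non-binary outcome at line %d", path, bad[1] + 1L)
  ph
}

#' @rdname read_write
#' @export
write_plink_raw <- function(genotypes, path) {
  hdr <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
           paste0(colnames(genotypes), "_A"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = " "), con)
  ids <- rownames(genotypes)
  body <- cbind(ids, ids, "0", "0", "0", "-9",
                matrix(as.character(genotypes), nrow(genotypes)))
  body[is.na(body)] <- "NA"
  writeLines(apply(body, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname read_write
#' @export
read_plink_raw <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) data_error("%s: empty RAW file", path)
  hdr <- strsplit(lines[1L], "[ \t]+")[[1L]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!identical(hdr[seq_along(fixed)], fixed))
    data_error("%s: line 1: not a PLINK RAW header", path)
  snp_ids <- sub("_[ACGT0-9]+$", "", hdr[-seq_along(fixed)])
  n_field <- length(hdr)
  rows <- strsplit(lines[-1L], "[ \t]+")
  geno <- matrix(NA_integer_, length(rows), length(snp_ids),
                 dimnames = list(NULL, snp_ids))
  ids <- character(length(rows))
  for (r in seq_along(rows)) {
    f <- rows[[r]]
    if (length(f) != n_field)
      data_error("%s: line %d: expected %d fields, found %d",
                 path, r + 1L, n_field, length(f))
    ids[r] <- f[2L]
    v <- f[-seq_along(fixed)]
    d <- suppressWarnings(as.integer(v))
    bad <- which(is.na(d) & v != "NA")
    if (length(bad))
      data_error("%s: line %d: bad dosage '%s'", path, r + 1L, v[bad[1]])
    geno[r, ] <- d
  }
  rownames(geno) <- ids
  geno
}

#' @rdname read_write
#' @export
write_plink_map <- function(snp_map, path) {
  write.table(data.frame(snp_map$chrom, snp_map$snp_id, 0L, snp_map$pos_bp),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname read_write
#' @export
read_plink_map <- function(path) {
  mp <- read.table(path, header = FALSE, sep = "\t",
                   colClasses = c("character", "character", "numeric",
                                  "integer"))
  if (ncol(mp) != 4L) data_error("%s: PLINK MAP needs 4 columns", path)
  data.frame(snp_id = mp[[2L]], chrom = mp[[1L]], pos_bp = mp[[4L]])
}

# ---- gene models (GFF3 / BED via rtracklayer) -------------------------------

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start, genes$end),
    strand = if ("strand" %in% names(genes)) genes$strand else "*",
    ID = genes$gene_id, Name = genes$gene_id, type = "gene")
}

#' @rdname read_write
#' @export
write_gene_models_gff3 <- function(genes, path) {
  gr <- genes_to_granges(genes)
  S4Vectors::mcols(gr)$source <- "liabscan"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname read_write
#' @export
write_gene_models_bed <- function(genes, path) {
  gr <- genes_to_granges(genes)
  names(gr) <- genes$gene_id
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' Both dialects are normalised to the internal 1-based closed convention
#' (rtracklayer performs the BED half-open conversion). For GFF3, rows of
#' type `gene` are kept when present; the gene id is taken from `ID` or
#' `Name`.
#'
#' @param path File path (`.gff3`/`.gff` or `.bed`, or use `format`).
#' @param format `"auto"`, `"gff3"` or `"bed"`.
#' @return Gene model `data.frame`: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = format)
  mc <- S4Vectors::mcols(gr)
  if (format == "gff3" && "type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% names(mc) && !all(is.na(mc$ID))) as.character(mc$ID)
         else if ("Name" %in% names(mc)) as.character(mc$Name)
         else if ("name" %in% names(mc)) as.character(mc$name)
         else data_error("%s: gene models carry no ID/Name attribute", path)
  data.frame(gene_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

# ---- gene sets (GMT) --------------------------------------------------------

#' @rdname read_write
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_write
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, as.character)
}

# ---- sparse symmetric matrices as coordinate-list text ----------------------

#' @rdname read_write
#' @export
write_matrix_coo <- function(m, path) {
  tm <- as(as(forceSymmetric(m), "generalMatrix"), "TsparseMatrix")
  lower <- tm@i >= tm@j
  df <- data.frame(i = tm@i[lower] + 1L, j = tm@j[lower] + 1L,
                   x = tm@x[lower])
  df <- df[order(df$i, df$j), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# symmetric ", nrow(m), " ",
                    paste(rownames(m), collapse = ",")), con)
  write.table(df, con, sep = " ", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname read_write
#' @export
read_matrix_coo <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# symmetric"))
    data_error("%s: line 1: missing coordinate-matrix header", path)
  meta <- strsplit(sub("^# symmetric ", "", first), " ")[[1L]]
  n <- as.integer(meta[1L])
  ids <- if (length(meta) >= 2L) strsplit(meta[2L], ",")[[1L]] else NULL
  dn <- if (length(ids) == n) list(ids, ids) else NULL
  df <- read.table(path, skip = 1L, col.names = c("i", "j", "x"))
  if (any(df$i < df$j))
    data_error("%s: upper-triangle entry found; expected lower triangle", path)
  Matrix::sparseMatrix(i = df$i, j = df$j, x = df$x, dims = c(n, n),
                       symmetric = TRUE, dimnames = dn)
}
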