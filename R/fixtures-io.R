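# Plain-text on-disk representation of a simulated study:
#   counts.tsv  genes x samples, first column gene_id, header = sample ids
#   counts.mtx + genes.txt + samples.txt   MatrixMarket coordinate encoding
#   metadata.csv  one row per sample, empty string = missing
#   annotation.tsv  gene_id, biotype
#   truth.json  per-gene effects + generator parameters

#' Write a simulated study to a directory
#'
#' @param dir Output directory (created if needed).
#' @param cohort Cohort table (`NA` written as empty string).
#' @param counts `DGEList` with `genes$biotype`.
#' @param truth Truth table from [gen_counts()] (optional).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, cohort, counts, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- counts$counts
  df <- data.frame(gene_id = rownames(cm), cm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(cm, sparse = TRUE),
                  file.path(dir, "counts.mtx"))
  writeLines(rownames(cm), file.path(dir, "genes.txt"))
  writeLines(colnames(cm), file.path(dir, "samples.txt"))
  write.csv(cohort, file.path(dir, "metadata.csv"), row.names = FALSE,
            na = "")
  write.table(counts$genes[, c("gene_id", "biotype")],
              file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(genes = truth, params = attr(truth, "params")),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

read_counts_tsv <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncol_expected <- length(header)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(vapply(body, length, 0L) != ncol_expected)
  if (length(bad))
    stop("counts.tsv line ", bad[1] + 1, ": expected ", ncol_expected,
         " fields, found ", length(body[[bad[1]]]))
  m <- matrix(0L, length(body), ncol_expected - 1L,
              dimnames = list(vapply(body, `[`, "", 1L), header[-1]))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.integer(body[[i]][-1]))
    if (anyNA(v))
      stop("counts.tsv line ", i + 1, ": non-integer count")
    m[i, ] <- v
  }
  m
}

#' Read a simulated study from a directory
#'
#' Prefers the MatrixMarket encoding when present (`format = "auto"`); the
#' TSV and MatrixMarket encodings decode to identical matrices.
#'
#' @param dir Directory written by [write_fixture()].
#' @param format `"auto"`, `"tsv"` or `"mtx"`.
#' @return List with `cohort`, `counts` (`DGEList`) and `truth` (or `NULL`).
#' @export
read_fixture <- function(dir, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  use_mtx <- switch(format,
    auto = file.exists(file.path(dir, "counts.mtx")),
    mtx = TRUE, tsv = FALSE)
  if (use_mtx) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    storage.mode(m) <- "integer"
    rownames(m) <- readLines(file.path(dir, "genes.txt"))
    colnames(m) <- readLines(file.path(dir, "samples.txt"))
  } else {
    m <- read_counts_tsv(file.path(dir, "counts.tsv"))
  }
  ann <- read.delim(file.path(dir, "annotation.tsv"),
                    stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = rownames(m),
                      biotype = ann$biotype[match(rownames(m),
                                                  ann$gene_id)],
                      row.names = rownames(m), stringsAsFactors = FALSE)
  cohort <- read.csv(file.path(dir, "metadata.csv"),
                     stringsAsFactors = FALSE, na.strings = "")
  for (nm in names(cohort)) {
    if (is.character(cohort[[nm]]) && nm != "sample_id")
      cohort[[nm]] <- factor(cohort[[nm]])
  }
  rownames(cohort) <- cohort$sample_id
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- as.data.frame(tr$genes, stringsAsFactors = FALSE)
    attr(truth, "params") <- tr$params
  }
  list(cohort = cohort,
       counts = edgeR::DGEList(counts = m, genes = genes),
       truth = truth)
}
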