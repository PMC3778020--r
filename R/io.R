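# TSV/BED readers and writers. External convention: BED intervals are
# 0-based half-open (width-1 intervals for point markers); internally marker
# positions are 1-based inclusive. Matrices travel as TSV with a header row
# and the row id in the first column; missing cells are empty strings.

#' Read a TSV matrix with row ids
#'
#' Expects a header row whose first field names the id column. Ragged rows
#' and duplicate ids are parse errors reported with their line number; empty
#' cells become NA.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1) stop("parse error: empty file ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  # a trailing empty cell is dropped by strsplit; pad to header width
  width <- length(cells[[1]])
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) < width) {
      cells[[i]] <- c(cells[[i]], rep("", width - length(cells[[i]])))
    } else if (length(cells[[i]]) > width) {
      stop("parse error: ragged row at line ", i, " of ", path)
    }
  }
  header <- cells[[1]][-1]
  ids <- vapply(cells[-1], `[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("parse error: duplicate id at line ",
         1 + which(duplicated(ids))[1], " of ", path)
  }
  body <- vapply(cells[-1], function(r) {
    x <- r[-1]
    x[x == ""] <- NA
    as.numeric(x)
  }, numeric(width - 1))
  m <- if (width - 1 == 1) matrix(body, ncol = 1) else t(body)
  dimnames(m) <- list(ids, header)
  m
}

#' Write a matrix as TSV with row ids
#'
#' @param m Matrix with dimnames.
#' @param path File path.
#' @param id_name Name of the id column (default "id").
#' @export
write_matrix <- function(m, path, id_name = "id") {
  body <- apply(m, 1:2, function(x) if (is.na(x)) "" else format(x, digits = 15))
  tab <- cbind(rownames(m), body)
  lines <- c(paste(c(id_name, colnames(m)), collapse = "\t"),
             apply(tab, 1, paste, collapse = "\t"))
  writeLines(lines, path)
}

#' Write a marker map as BED
#'
#' Internal 1-based positions become 0-based half-open width-1 intervals.
#'
#' @param map data.frame: marker, chrom, pos.
#' @param path File path.
#' @export
write_marker_bed <- function(map, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", map$chrom, map$pos - 1L, map$pos,
                   map$marker)
  writeLines(lines, path)
}

#' Read a BED marker map
#'
#' @param path File path.
#' @return data.frame: marker, chrom, pos (1-based).
#' @export
read_marker_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "marker"),
                           stringsAsFactors = FALSE)
  if (any(tab$end - tab$start != 1)) {
    stop("parse error: point markers must be width-1 BED intervals")
  }
  data.frame(marker = tab$marker, chrom = tab$chrom, pos = tab$start + 1L,
             stringsAsFactors = FALSE)
}

#' Write QTL regions as BED
#'
#' @param regions data.frame from \code{\link{call_qtl_regions}}.
#' @param path File path.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%g", regions$chrom, regions$start - 1L,
                   regions$end, regions$peak_marker, regions$peak_p)
  writeLines(lines, path)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path File path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV data.frame
#' @param path File path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a full synthetic dataset to a run directory
#'
#' Genotypes, marker map (BED), growth, one expression TSV per environment
#' (missing cells empty), the deletion assay table and a ground-truth sidecar
#' JSON. The truth sidecar exists for benchmarking only; no pipeline stage
#' reads it.
#'
#' @param dir Output directory (created if needed).
#' @param genotypes \code{GenotypeMatrix}.
#' @param phenotypes \code{MultiEnvPhenotypes}.
#' @param assay Deletion-assay data.frame (optional).
#' @param truth Truth sidecar list/data.frame (optional).
#' @export
write_dataset <- function(dir, genotypes, phenotypes, assay = NULL,
                          truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(genotypes$alleles, file.path(dir, "genotypes.tsv"),
               id_name = "segregant")
  write_marker_bed(genotypes$map, file.path(dir, "markers.bed"))
  write_matrix(phenotypes$growth, file.path(dir, "growth.tsv"),
               id_name = "segregant")
  for (ev in phenotypes$environments) {
    write_matrix(phenotypes$expression[, , ev],
                 file.path(dir, paste0("expression_", ev, ".tsv")),
                 id_name = "segregant")
  }
  if (!is.null(assay)) write_tsv(assay, file.path(dir, "deletion_assay.tsv"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Read a dataset from a run directory
#'
#' @param dir Directory written by \code{\link{write_dataset}}.
#' @return list: genotypes (\code{GenotypeMatrix}), phenotypes
#'   (\code{MultiEnvPhenotypes}), assay (or NULL).
#' @export
read_dataset <- function(dir) {
  alleles <- read_matrix(file.path(dir, "genotypes.tsv"))
  map <- read_marker_bed(file.path(dir, "markers.bed"))
  if (!identical(colnames(alleles), map$marker)) {
    stop("genotype columns do not match the marker map")
  }
  genotypes <- structure(list(alleles = alleles, map = map),
                         class = "GenotypeMatrix")
  growth <- read_matrix(file.path(dir, "growth.tsv"))
  efiles <- sort(list.files(dir, pattern = "^expression_.*\\.tsv$"))
  envs <- sub("^expression_(.*)\\.tsv$", "\\1", efiles)
  # keep the growth column order where possible
  envs <- c(intersect(colnames(growth), envs), setdiff(envs, colnames(growth)))
  exl <- lapply(envs, function(ev) {
    read_matrix(file.path(dir, paste0("expression_", ev, ".tsv")))
  })
  genes <- colnames(exl[[1]])
  expr <- array(NA_real_, c(nrow(growth), length(genes), length(envs)),
                dimnames = list(rownames(growth), genes, envs))
  for (i in seq_along(envs)) expr[, , i] <- exl[[i]][rownames(growth), ]
  mask <- !apply(expr, c(1, 3), function(x) all(is.na(x)))
  phen <- structure(list(growth = growth, expression = expr, mask = mask,
                         environments = envs),
                    class = "MultiEnvPhenotypes")
  assay_path <- file.path(dir, "deletion_assay.tsv")
  assay <- if (file.exists(assay_path)) read_tsv(assay_path) else NULL
  list(genotypes = genotypes, phenotypes = phen, assay = assay)
}
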