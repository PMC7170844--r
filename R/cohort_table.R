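#' Longitudinal sample-by-OTU cohort table
#'
#' A `cohort_table` bundles a non-negative integer count matrix
#' (samples in rows, OTUs in columns) with per-sample metadata and an
#' optional taxonomy map. It is the universal input of every analysis in
#' this package.
#'
#' Required metadata columns are `sample_id`, `animal_id`, `day_of_life`
#' (integer days since birth, 0-based), `diet_code` and `delivery_mode`
#' (`"vaginal"` or `"c-section"`). `sex` (`"F"`/`"M"`) and `time_bin` are
#' optional; `time_bin` is usually added later by [assign_time_bins()].
#'
#' @param counts numeric matrix of non-negative whole numbers, samples x
#'   OTUs, with unique row and column names.
#' @param metadata data.frame with one row per sample. May carry sample ids
#'   either in a `sample_id` column or as row names.
#' @param taxonomy optional taxonomy map, see [read_taxonomy()].
#' @param horizon maximum permitted `day_of_life` (default 831).
#' @return an object of class `cohort_table`: a list with elements
#'   `counts`, `metadata`, `taxonomy` and `horizon`.
#' @seealso [load_cohort()], [filter_rare()], [rarefy()],
#'   [assign_time_bins()], [to_relative_abundance()]
#' @export
cohort_table <- function(counts, metadata, taxonomy = NULL, horizon = 831L) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in counts")
  if (any(!is.finite(counts)))
    stop("counts must be finite")
  if (any(counts < 0))
    stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be whole numbers")
  storage.mode(counts) <- "integer"

  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% names(metadata)) {
    if (is.null(rownames(metadata)))
      stop("metadata needs a sample_id column or row names")
    metadata$sample_id <- rownames(metadata)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata")
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- metadata$sample_id

  for (col in c("animal_id", "day_of_life", "diet_code", "delivery_mode")) {
    if (!col %in% names(metadata))
      stop("metadata lacks required column: ", col)
  }
  metadata$animal_id <- as.character(metadata$animal_id)
  metadata$day_of_life <- as.integer(metadata$day_of_life)
  if (any(is.na(metadata$day_of_life)) || any(metadata$day_of_life < 0))
    stop("day_of_life must be integer days >= 0")
  if (any(metadata$day_of_life > horizon))
    stop("day_of_life exceeds horizon (", horizon, ")")
  metadata$diet_code <- as.character(metadata$diet_code)
  metadata$delivery_mode <- as.character(metadata$delivery_mode)
  bad_mode <- setdiff(unique(metadata$delivery_mode), c("vaginal", "c-section"))
  if (length(bad_mode))
    stop("delivery_mode must be 'vaginal' or 'c-section', got: ",
         paste(bad_mode, collapse = ", "))
  if ("sex" %in% names(metadata)) {
    metadata$sex <- as.character(metadata$sex)
    bad_sex <- setdiff(unique(metadata$sex), c("F", "M", NA))
    if (length(bad_sex)) stop("sex must be 'F' or 'M'")
  }
  if (!is.null(taxonomy)) taxonomy <- validate_taxonomy(taxonomy)

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                 horizon = as.integer(horizon)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  cat("  animals:", length(unique(x$metadata$animal_id)),
      " days:", min(x$metadata$day_of_life), "-", max(x$metadata$day_of_life),
      "\n")
  md <- table(x$metadata$delivery_mode)
  cat("  delivery:", paste(names(md), md, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$metadata$time_bin))
    cat("  time bins:", length(unique(x$metadata$time_bin)), "\n")
  if (!is.null(x$taxonomy))
    cat("  taxonomy:", nrow(x$taxonomy), "OTUs classified\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$counts)

#' Subset a cohort table
#'
#' @param x a [cohort_table()].
#' @param i sample selector (names, indices or logical).
#' @param j OTU selector.
#' @param ... ignored.
#' @return the subsetted `cohort_table`.
#' @export
`[.cohort_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  meta <- x$metadata[match(rownames(counts), x$metadata$sample_id), ,
                     drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[tax$otu_id %in% colnames(counts), ,
                                drop = FALSE]
  out <- x
  out$counts <- counts
  out$metadata <- meta
  out$taxonomy <- tax
  out
}

# ranks used by Greengenes-style lineage strings
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

validate_taxonomy <- function(taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  if (!"otu_id" %in% names(taxonomy))
    stop("taxonomy needs an otu_id column")
  miss <- setdiff(TAX_RANKS, names(taxonomy))
  if (length(miss)) stop("taxonomy lacks ranks: ", paste(miss, collapse = ", "))
  taxonomy$otu_id <- as.character(taxonomy$otu_id)
  if (anyDuplicated(taxonomy$otu_id)) stop("duplicate otu ids in taxonomy")
  for (r in TAX_RANKS) {
    v <- as.character(taxonomy[[r]])
    v[is.na(v)] <- ""
    taxonomy[[r]] <- v
  }
  # a rank may be empty only if all deeper ranks are empty
  mat <- as.matrix(taxonomy[TAX_RANKS]) != ""
  if (nrow(mat)) {
    ok <- apply(mat, 1, function(z) {
      filled <- which(z)
      length(filled) == 0L || all(seq_len(max(filled)) %in% filled)
    })
    if (!all(ok))
      stop("taxonomy has a gap: an empty rank above a filled one (otu ",
           paste(utils::head(taxonomy$otu_id[!ok], 3), collapse = ", "), ")")
  }
  taxonomy
}

parse_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    vals <- character(7)
    for (k in seq_len(min(length(p), 7))) {
      v <- p[k]
      v <- sub(paste0("^", prefixes[k]), "", v)
      vals[k] <- v
    }
    vals
  }, character(7)))
  colnames(out) <- TAX_RANKS
  as.data.frame(out)
}

format_lineage <- function(taxonomy) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  apply(as.matrix(taxonomy[TAX_RANKS]), 1, function(v)
    paste0(prefixes, v, collapse = "; "))
}

#' Read a taxonomy table
#'
#' Reads a two-column TSV mapping OTU ids to Greengenes-style 7-rank
#' lineage strings (`k__...; p__...; ...`).
#'
#' @param path path to the taxonomy TSV (no header, or a header line
#'   starting with `#`).
#' @return a data.frame with columns `otu_id` and the seven ranks
#'   `domain` ... `species`; missing ranks are empty strings.
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("otu_id", "lineage"))
  tax <- cbind(otu_id = as.character(raw$otu_id), parse_lineage(raw$lineage))
  validate_taxonomy(tax)
}

#' Load a cohort from an OTU table, a mapfile and optional taxonomy
#'
#' The OTU table may be a TSV in either orientation (`#OTU ID` header
#' dialect, OTUs x samples, or samples x OTUs -- detected from the header)
#' or a BIOM file (read through the biomformat package). Metadata is a
#' QIIME-style mapfile TSV whose first column (`#SampleID`) keys samples.
#'
#' @param table_path path to the OTU table (`.tsv`/`.txt` or `.biom`).
#' @param metadata_path path to the mapfile TSV.
#' @param taxonomy_path optional taxonomy TSV, see [read_taxonomy()].
#' @param horizon maximum permitted day of life.
#' @return a validated [cohort_table()] oriented samples x OTUs.
#' @export
load_cohort <- function(table_path, metadata_path, taxonomy_path = NULL,
                        horizon = 831L) {
  metadata <- read_mapfile(metadata_path)
  counts <- read_otu_table(table_path, sample_ids = metadata$sample_id)
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy(taxonomy_path)
  cohort_table(counts, metadata, taxonomy = taxonomy, horizon = horizon)
}

read_mapfile <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  md <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                          quote = "", stringsAsFactors = FALSE,
                          colClasses = "character")
  names(md) <- cols
  names(md)[1] <- "sample_id"
  md
}

read_otu_table <- function(path, sample_ids) {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    return(t(m))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           comment.char = "", quote = "", skip = 0L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  # "#OTU ID" dialect: strip a leading constructed name
  m <- as.matrix(raw)
  if (!is.numeric(m)) stop("OTU table contains non-numeric entries")
  n_col_hits <- sum(colnames(m) %in% sample_ids)
  n_row_hits <- sum(rownames(m) %in% sample_ids)
  if (n_col_hits >= n_row_hits && n_col_hits > 0) {
    t(m)          # table was OTUs x samples
  } else if (n_row_hits > 0) {
    m             # already samples x OTUs
  } else {
    stop("no sample ids shared between OTU table and metadata")
  }
}

#' Write a cohort to disk
#'
#' Writes the OTU table (TSV `#OTU ID` dialect, OTUs x samples, or BIOM
#' JSON), a QIIME-style mapfile, and the taxonomy if present. Formats are
#' the same dialects [load_cohort()] reads, so write -> load round-trips.
#'
#' @param table a [cohort_table()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param format `"tsv"` or `"biom"` for the OTU table.
#' @return invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(table, dir, prefix = "cohort",
                         format = c("tsv", "biom")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM files requires the biomformat package")
    fp <- file.path(dir, paste0(prefix, "_otu_table.biom"))
    biomformat::write_biom(biomformat::make_biom(t(table$counts)), fp)
    files["table"] <- fp
  } else {
    fp <- file.path(dir, paste0(prefix, "_otu_table.tsv"))
    tm <- t(table$counts)
    con <- file(fp, "w")
    writeLines(paste(c("#OTU ID", colnames(tm)), collapse = "\t"), con)
    utils::write.table(tm, con, sep = "\t", quote = FALSE,
                       col.names = FALSE, row.names = TRUE)
    close(con)
    files["table"] <- fp
  }
  mp <- file.path(dir, paste0(prefix, "_mapfile.tsv"))
  md <- table$metadata
  first <- md["sample_id"]
  rest <- md[setdiff(names(md), "sample_id")]
  con <- file(mp, "w")
  writeLines(paste(c("#SampleID", names(rest)), collapse = "\t"), con)
  utils::write.table(cbind(first, rest), con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = FALSE)
  close(con)
  files["metadata"] <- mp
  if (!is.null(table$taxonomy)) {
    tp <- file.path(dir, paste0(prefix, "_taxonomy.tsv"))
    utils::write.table(
      data.frame(table$taxonomy$otu_id, format_lineage(table$taxonomy)),
      tp, sep = "\t", quote = FALSE, col.names = FALSE, row.names = FALSE)
    files["taxonomy"] <- tp
  }
  invisible(files)
}
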