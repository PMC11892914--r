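#' Construct an OTU count table
#'
#' Container for a taxa-by-samples matrix of nonnegative integer counts with
#' per-taxon taxonomy and phylum annotations and an optional per-sample group
#' label. This is the object every microbiome stage of the pipeline consumes.
#'
#' @param counts numeric matrix, taxa in rows, samples in columns; entries
#'   must be nonnegative integers. Row and column names are required and must
#'   be unique.
#' @param taxonomy character vector of species names, one per taxon. Defaults
#'   to the row names of `counts`.
#' @param phylum optional character vector of phylum names, one per taxon
#'   (needed for the Firmicutes/Bacteroidetes ratio).
#' @param sample_group optional factor/character of group labels
#'   (e.g. `"control"`, `"dementia"`), one per sample.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `phylum`, `sample_group`.
#' @export
otu_table <- function(counts, taxonomy = rownames(counts), phylum = NULL,
                      sample_group = NULL) {
  counts <- as.matrix(counts)
  # empty (fully filtered) tables are legal; R normalizes zero-length
  # dimnames to NULL, so only require names when taxa are present
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("'counts' must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids in 'counts'")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in 'counts'")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be nonnegative integers")
  ntax <- nrow(counts)
  taxonomy <- as.character(taxonomy)
  if (length(taxonomy) != ntax)
    stop("'taxonomy' must have one entry per taxon")
  if (!is.null(phylum)) {
    phylum <- as.character(phylum)
    if (length(phylum) != ntax) stop("'phylum' must have one entry per taxon")
    names(phylum) <- rownames(counts)
  }
  if (!is.null(sample_group)) {
    sample_group <- as.character(sample_group)
    if (length(sample_group) != ncol(counts))
      stop("'sample_group' must have one entry per sample")
    names(sample_group) <- colnames(counts)
  }
  names(taxonomy) <- rownames(counts)
  structure(list(counts = counts, taxonomy = taxonomy, phylum = phylum,
                 sample_group = sample_group),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table:", nrow(x$counts), "taxa x", ncol(x$counts), "samples\n")
  if (!is.null(x$sample_group))
    print(table(group = x$sample_group))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Subset an OTU table by taxa and/or samples
#'
#' @param x an [otu_table()].
#' @param taxa,samples character or logical/integer index vectors.
#' @return A new `otu_table`.
#' @export
subset_otu <- function(x, taxa = NULL, samples = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (is.null(taxa)) taxa <- seq_len(nrow(x$counts))
  if (is.null(samples)) samples <- seq_len(ncol(x$counts))
  counts <- x$counts[taxa, samples, drop = FALSE]
  otu_table(counts,
            taxonomy = x$taxonomy[taxa],
            phylum = if (!is.null(x$phylum)) x$phylum[taxa],
            sample_group = if (!is.null(x$sample_group)) x$sample_group[samples])
}

#' Drop low-count taxa by total abundance
#'
#' Retains taxa whose total count across all samples is strictly greater than
#' `min_total` (the species-table filtration rule: "total count of more than
#' 10"). The sample set is unchanged. If every taxon is removed an empty
#' table is returned with a warning rather than an error.
#'
#' @param table an [otu_table()].
#' @param min_total count threshold; strict inequality.
#' @return Filtered `otu_table`.
#' @export
filter_by_total <- function(table, min_total = 10) {
  stopifnot(inherits(table, "otu_table"))
  keep <- rowSums(table$counts) > min_total
  if (!any(keep))
    warning("all taxa removed: no taxon has total count > ", min_total)
  subset_otu(table, taxa = keep)
}

#' Per-sample relative abundance
#'
#' Closes each sample (column) to proportions. Every sample must have a
#' positive total.
#'
#' @param table an [otu_table()].
#' @return Numeric matrix of proportions, same dimnames as the counts; each
#'   column sums to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  tot <- colSums(table$counts)
  bad <- names(tot)[tot == 0]
  if (length(bad))
    stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  sweep(table$counts, 2, tot, "/")
}

#' Abundance/incidence summary of the core microbiota
#'
#' For each of the `top_n` most abundant taxa (ranked by overall mean
#' relative abundance) reports, per group, the mean relative abundance (%)
#' and the incidence (%): the share of the group's samples in which the
#' taxon's relative abundance is strictly greater than `threshold`.
#'
#' @param props proportion matrix from [relative_abundance()] (taxa x samples).
#' @param groups group label per sample.
#' @param threshold abundance threshold for presence; strict inequality
#'   (default 0.01, i.e. ">1%").
#' @param top_n number of taxa reported, ranked by overall mean abundance;
#'   ties broken by taxon name.
#' @return data.frame with columns `taxon`, `group`, `abundance_pct`,
#'   `incidence_pct`.
#' @export
incidence_summary <- function(props, groups, threshold = 0.01, top_n = 15) {
  props <- as.matrix(props)
  groups <- as.character(groups)
  if (length(groups) != ncol(props))
    stop("'groups' must label every sample")
  if (any(table(groups) == 0) || length(unique(groups)) < 1)
    stop("empty group")
  overall <- rowMeans(props)
  ord <- order(-overall, rownames(props))
  top <- utils::head(ord, top_n)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    if (!length(idx)) stop("empty group: ", g)
    sub <- props[top, idx, drop = FALSE]
    data.frame(taxon = rownames(props)[top],
               group = g,
               abundance_pct = 100 * rowMeans(sub),
               incidence_pct = 100 * rowMeans(sub > threshold),
               row.names = NULL)
  }))
  out
}

#' Per-sample log Firmicutes/Bacteroidetes ratio
#'
#' Natural log of the ratio of total Firmicutes counts to total Bacteroidetes
#' counts in each sample. Samples in which either phylum total is zero get
#' `NA` (flagged undefined) and should be excluded pairwise downstream.
#'
#' @param table an [otu_table()] with phylum annotations.
#' @return Named numeric vector, one value per sample; `NA` where undefined.
#' @export
fb_ratio <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (is.null(table$phylum))
    stop("phylum annotations are required for the F/B ratio")
  f <- colSums(table$counts[table$phylum == "Firmicutes", , drop = FALSE])
  b <- colSums(table$counts[table$phylum == "Bacteroidetes", , drop = FALSE])
  out <- ifelse(f > 0 & b > 0, log(f / b), NA_real_)
  if (anyNA(out))
    warning("F/B ratio undefined for sample(s): ",
            paste(colnames(table$counts)[is.na(out)], collapse = ", "))
  names(out) <- colnames(table$counts)
  out
}

#' Read / write the OTU table TSV format
#'
#' Tab-separated, taxa in rows: a `taxon` id column, one column per sample,
#' then `taxonomy` and `phylum` annotation columns.
#'
#' @param path file path.
#' @param table an [otu_table()].
#' @param sample_group optional group labels to attach on read.
#' @return `read_otu_tsv` returns an `otu_table`; `write_otu_tsv` returns
#'   `path` invisibly.
#' @export
write_otu_tsv <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(taxon = rownames(table$counts), table$counts,
                   taxonomy = table$taxonomy,
                   phylum = if (is.null(table$phylum)) NA else table$phylum,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(path, sample_group = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  ann <- c("taxon", "taxonomy", "phylum")
  samp <- setdiff(colnames(df), ann)
  counts <- as.matrix(df[, samp, drop = FALSE])
  rownames(counts) <- df$taxon
  phy <- if (all(is.na(df$phylum))) NULL else df$phylum
  otu_table(counts, taxonomy = df$taxonomy, phylum = phy,
            sample_group = sample_group)
}
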