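#' Assemblage count table
#'
#' A `count_table` is a non-negative integer matrix with taxa as rows and
#' samples as columns, carrying a per-taxon size-class/domain label.  It is
#' the common currency of the pipeline: per-domain OTU tables, faunal species
#' tables and combined multi-domain tables all use this orientation (taxa in
#' rows, samples in columns) so no stage has to guess.
#'
#' @param values numeric matrix, taxa x samples, non-negative integers.
#'   Row names are taxon ids, column names sample ids; both mandatory and
#'   unique.
#' @param domain either a single label recycled over taxa or a character
#'   vector with one label per taxon.  Must be drawn from
#'   `c("bacteria", "archaea", "microeukarya", "meiofauna", "macrofauna")`.
#' @return a `count_table` object (matrix subclass with a `domain` attribute).
#' @examples
#' m <- matrix(c(0L, 3L, 5L, 2L), 2, 2,
#'             dimnames = list(c("otu1", "otu2"), c("s1", "s2")))
#' count_table(m, "bacteria")
#' @export
count_table <- function(values, domain) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count_table needs taxon row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate taxon id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(values - round(values)) > 1e-8))
    stop("counts must be integer-valued")
  storage.mode(values) <- "double"
  domain <- as.character(domain)
  if (length(domain) == 1L) domain <- rep(domain, nrow(values))
  if (length(domain) != nrow(values))
    stop("domain must have one label per taxon")
  bad <- setdiff(unique(domain), corecomm_domains())
  if (length(bad))
    stop("unknown domain label: ", paste(bad, collapse = ", "))
  structure(values, domain = domain, class = c("count_table", class(values)))
}

#' Recognized size-class/domain labels
#' @return character vector of the five labels, microbial first.
#' @export
corecomm_domains <- function() {
  c("bacteria", "archaea", "microeukarya", "meiofauna", "macrofauna")
}

#' @export
`[.count_table` <- function(x, i, j, ..., drop = FALSE) {
  dom <- attr(x, "domain")
  lin <- attr(x, "lineage")
  mem <- attr(x, "members")
  y <- NextMethod(drop = drop)
  if (is.matrix(y)) {
    idx <- if (missing(i)) seq_along(dom)
           else if (is.character(i)) match(i, rownames(unclass(x)))
           else seq_along(dom)[i]
    y <- structure(y, domain = dom[idx],
                   class = c("count_table", class(y)))
    if (!is.null(lin)) attr(y, "lineage") <- lin[idx]
    if (!is.null(mem)) attr(y, "members") <- mem[idx]
    return(y)
  }
  y
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(unique(attr(x, "domain")), collapse = ", ")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))),
                   drop = FALSE])
  invisible(x)
}

#' Per-taxon domain labels of a count table
#' @param x a `count_table`
#' @return character vector, one label per row of `x`
#' @export
taxon_domains <- function(x) {
  d <- attr(x, "domain")
  if (is.null(d)) stop("object carries no domain labels")
  d
}

#' Read a count table from TSV
#'
#' Expects a header row of sample ids, a first column of taxon ids and
#' integer counts in the remaining cells (the transposed mothur-shared
#' convention: taxa in rows).
#'
#' @param path TSV file
#' @param domain_label domain for every taxon in the file
#' @return a validated [count_table()]
#' @export
read_count_table <- function(path, domain_label) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no taxa in ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(df[-1], is.numeric, logical(1))]
    stop("non-numeric counts in column(s): ", paste(bad, collapse = ", "))
  }
  rownames(m) <- ids
  count_table(m, domain_label)
}

#' Write a count table to TSV
#' @param x a `count_table` (or taxa x samples matrix)
#' @param path output file
#' @param id_column header for the taxon-id column
#' @export
write_count_table <- function(x, path, id_column = "taxon") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Metadata carries the habitat context per sample: basal fluid temperature
#' (degrees C; NA allowed for background fluids), substratum
#' (sulphide/basalt/na), location, and sample type (tubeworm_grab,
#' diffuse_fluid, background_fluid).
#'
#' @param path TSV with columns sample_id, basal_temperature, substratum,
#'   location, sample_type
#' @return data.frame of validated metadata
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("sample_id", "basal_temperature", "substratum", "location",
            "sample_type")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata")
  ok_type <- c("tubeworm_grab", "diffuse_fluid", "background_fluid")
  if (any(!md$sample_type %in% ok_type))
    stop("sample_type must be one of: ", paste(ok_type, collapse = ", "))
  ok_sub <- c("sulphide", "basalt", "na")
  if (any(!md$substratum %in% ok_sub))
    stop("substratum must be one of: ", paste(ok_sub, collapse = ", "))
  tt <- md$basal_temperature
  if (any(!is.na(tt) & tt < 0)) stop("negative basal temperature")
  md
}

#' Write sample metadata TSV
#' @param md metadata data.frame
#' @param path output file
#' @export
write_sample_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Two-column TSV: taxon id and a semicolon-delimited lineage
#' (domain;phylum;...;genus), possibly truncated at shallow ranks.
#'
#' @param path TSV file
#' @return named character vector taxon id -> lineage string
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("taxonomy file needs id and lineage columns")
  lin <- as.character(df[[2]])
  if (any(!nzchar(lin))) stop("empty lineage for: ",
                              paste(df[[1]][!nzchar(lin)], collapse = ", "))
  stats::setNames(lin, as.character(df[[1]]))
}

#' Write a taxonomy table TSV
#' @param taxonomy named character vector (id -> lineage)
#' @param path output file
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(
    data.frame(taxon = names(taxonomy), lineage = unname(taxonomy)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read qPCR domain fractions
#'
#' @param path TSV with columns sample_id, bacteria, archaea, microeukarya
#'   (fractions in \[0, 1\] summing to ~1 per sample)
#' @return sample x domain matrix of fractions
#' @export
read_domain_fractions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "bacteria", "archaea", "microeukarya")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fractions file missing column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(df[, c("bacteria", "archaea", "microeukarya")])
  rownames(m) <- df$sample_id
  validate_domain_fractions(m)
}

#' Validate a sample x domain fraction matrix
#'
#' Fractions must lie in \[0, 1\] and sum to 1 within 0.02 per sample
#' (published tables carry rounding).
#'
#' @param m sample x domain matrix with columns bacteria, archaea,
#'   microeukarya
#' @return the matrix, invisibly checked
#' @export
validate_domain_fractions <- function(m) {
  if (any(m < 0 | m > 1)) stop("domain fractions must lie in [0, 1]")
  s <- rowSums(m)
  off <- which(abs(s - 1) > 0.02)
  if (length(off))
    stop("domain fractions do not sum to 1 (within 0.02) for: ",
         paste(rownames(m)[off], collapse = ", "))
  m
}

#' Write qPCR domain fractions TSV
#' @param m sample x domain matrix
#' @param path output file
#' @export
write_domain_fractions <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align count tables on their shared samples
#'
#' Restricts a set of count tables (and optional metadata) to the samples
#' they all share, in one common column order, reporting what was dropped.
#' Needed because individual domains can lose samples (e.g. a domain
#' sequenced too shallowly in one sample).
#'
#' @param tables named list of `count_table`s
#' @param metadata optional metadata data.frame; if given, alignment is also
#'   restricted to samples present in it
#' @return list with `tables` (aligned), `samples` (common order) and
#'   `dropped` (named list of sample ids dropped from each table)
#' @export
align_samples <- function(tables, metadata = NULL) {
  stopifnot(length(tables) >= 1L)
  sets <- lapply(tables, colnames)
  shared <- Reduce(intersect, sets)
  if (!is.null(metadata)) shared <- intersect(shared, metadata$sample_id)
  if (length(shared) == 0L) stop("no samples shared across tables")
  shared <- sets[[1]][sets[[1]] %in% shared]  # stable order
  dropped <- lapply(sets, setdiff, y = shared)
  aligned <- lapply(tables, function(x) x[, shared, drop = FALSE])
  list(tables = aligned, samples = shared, dropped = dropped)
}
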