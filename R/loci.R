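#' Construct a table of microRNA precursor loci
#'
#' The central container of the package is a plain `data.frame` with one row
#' per microRNA precursor (the hairpin-forming genomic feature). Coordinates
#' follow the GFF3 convention: 1-based, both ends inclusive.
#'
#' @param mirna_id Character vector of precursor identifiers
#'   (e.g. `"dme-mir-999"`). Must be unique within a species; the same
#'   identifier in two species denotes orthologous loci.
#' @param species_id Short species code (e.g. `"dme"`). Recycled if scalar.
#' @param chrom Sequence (chromosome/scaffold) name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param annotation_family Family label in the database (miRBase-style)
#'   sense, used for cluster composition statistics. Defaults to `mirna_id`.
#' @param phylo_family Family label in the phylogenetic sense, used by the
#'   origin classifier; may merge annotation families. Defaults to
#'   `annotation_family`.
#' @param host_transcript Optional identifier of the primary transcript
#'   containing the locus.
#' @param ortholog_group Optional finer-than-family grouping identifying
#'   orthologous copies across species (paralogs of one family may belong to
#'   different groups). Used for per-microRNA age inference; defaults to
#'   `phylo_family`.
#'
#' @return A validated `data.frame` of class `mirna_loci`.
#' @seealso [read_mirna_gff3()], [call_clusters()]
#' @export
mirna_loci <- function(mirna_id, species_id, chrom, start, end, strand,
                       annotation_family = NULL, phylo_family = NULL,
                       host_transcript = NA_character_,
                       ortholog_group = NULL) {
  mirna_id <- as.character(mirna_id)
  if (is.null(annotation_family)) annotation_family <- mirna_id
  if (is.null(phylo_family)) phylo_family <- annotation_family
  if (is.null(ortholog_group)) ortholog_group <- phylo_family
  df <- data.frame(
    mirna_id = mirna_id,
    species_id = as.character(species_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    annotation_family = as.character(annotation_family),
    phylo_family = as.character(phylo_family),
    host_transcript = as.character(host_transcript),
    ortholog_group = as.character(ortholog_group),
    stringsAsFactors = FALSE
  )
  validate_mirna_loci(df)
}

#' Validate a `mirna_loci` table
#'
#' Checks the container invariants: `start <= end`, strand in `{+, -}`,
#' identifiers unique within each species, family labels non-empty.
#'
#' @param df A data.frame with at least the `mirna_loci` columns.
#' @return The input, classed `mirna_loci`, invisibly usable downstream.
#' @export
validate_mirna_loci <- function(df) {
  required <- c("mirna_id", "species_id", "chrom", "start", "end", "strand",
                "annotation_family", "phylo_family")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("mirna_loci: missing columns: ", paste(missing, collapse = ", "))
  if (!"host_transcript" %in% names(df)) df$host_transcript <- NA_character_
  if (!"ortholog_group" %in% names(df)) df$ortholog_group <- df$phylo_family
  if (nrow(df) > 0) {
    if (any(df$start > df$end))
      stop("mirna_loci: start > end for: ",
           paste(df$mirna_id[df$start > df$end], collapse = ", "))
    if (!all(df$strand %in% c("+", "-")))
      stop("mirna_loci: strand must be '+' or '-'")
    key <- paste(df$species_id, df$mirna_id)
    if (anyDuplicated(key))
      stop("mirna_loci: duplicate mirna_id within a species: ",
           paste(unique(df$mirna_id[duplicated(key)]), collapse = ", "))
    if (any(!nzchar(df$annotation_family)) || any(is.na(df$annotation_family)) ||
        any(!nzchar(df$phylo_family)) || any(is.na(df$phylo_family)))
      stop("mirna_loci: family labels must be non-empty")
  }
  class(df) <- unique(c("mirna_loci", class(df)))
  df
}

GFF3_PRECURSOR_TYPE <- "miRNA_primary_transcript"

#' Read microRNA precursor loci from a GFF3 file (miRBase dialect)
#'
#' Keeps rows whose feature type equals `feature_type` (by default the
#' miRBase `miRNA_primary_transcript` precursor records; mature `miRNA`
#' rows are skipped). Coordinates are kept 1-based inclusive as in GFF3.
#' The precursor name is taken from the `Name` attribute, falling back to
#' `ID`. Family labels are read from `annotation_family` / `phylo_family`
#' attributes when present (as written by [write_mirna_gff3()]); otherwise
#' they default to the precursor name.
#'
#' @param path Path to a GFF3 file.
#' @param species_id Species code attached to every locus.
#' @param feature_type GFF3 type column value identifying precursor rows.
#' @return A `mirna_loci` table.
#' @export
read_mirna_gff3 <- function(path, species_id,
                            feature_type = GFF3_PRECURSOR_TYPE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- vector("list", length(idx))
  n <- 0L
  for (i in idx) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop("malformed GFF3 at line ", i, ": expected 9 tab-separated fields, got ",
           length(f))
    if (f[3] != feature_type) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end))
      stop("malformed GFF3 at line ", i, ": non-numeric coordinates")
    attrs <- parse_gff3_attributes(f[9], line = i)
    id <- attrs[["Name"]]
    if (is.null(id)) id <- attrs[["ID"]]
    if (is.null(id))
      stop("malformed GFF3 at line ", i, ": no ID or Name attribute")
    n <- n + 1L
    rows[[n]] <- list(
      mirna_id = id, chrom = f[1], start = start, end = end, strand = f[7],
      annotation_family = attrs[["annotation_family"]] %||% id,
      phylo_family = attrs[["phylo_family"]] %||%
        (attrs[["annotation_family"]] %||% id),
      host_transcript = attrs[["host_transcript"]] %||% NA_character_,
      ortholog_group = attrs[["ortholog_group"]] %||% NA_character_
    )
  }
  rows <- rows[seq_len(n)]
  if (n == 0L) {
    return(mirna_loci(character(), character(), character(), integer(),
                      integer(), character()))
  }
  get <- function(fld) vapply(rows, function(r) r[[fld]], rows[[1]][[fld]])
  ids <- vapply(rows, function(r) r$mirna_id, "")
  if (anyDuplicated(ids))
    stop("duplicate precursor ID in GFF3: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  og <- get("ortholog_group")
  pf <- get("phylo_family")
  og[is.na(og)] <- pf[is.na(og)]
  mirna_loci(
    mirna_id = ids, species_id = species_id, chrom = get("chrom"),
    start = vapply(rows, function(r) r$start, 1L),
    end = vapply(rows, function(r) r$end, 1L),
    strand = get("strand"),
    annotation_family = get("annotation_family"),
    phylo_family = pf,
    host_transcript = get("host_transcript"),
    ortholog_group = og
  )
}

parse_gff3_attributes <- function(s, line = NA) {
  if (!nzchar(s) || s == ".") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2)
      stop("malformed GFF3 at line ", line, ": bad attribute '", p, "'")
    out[[trimws(kv[1])]] <- utils::URLdecode(paste(kv[-1], collapse = "="))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write microRNA precursor loci as GFF3
#'
#' Emits one `miRNA_primary_transcript` row per locus with `ID`, `Name`,
#' `annotation_family`, `phylo_family` (and, when informative,
#' `host_transcript` and `ortholog_group`) attributes, so that
#' read-write-read round-trips are the identity.
#'
#' @param loci A `mirna_loci` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mirna_gff3 <- function(loci, path) {
  loci <- validate_mirna_loci(loci)
  header <- "##gff-version 3"
  attr_of <- function(i) {
    a <- sprintf("ID=%s;Name=%s;annotation_family=%s;phylo_family=%s",
                 loci$mirna_id[i], loci$mirna_id[i],
                 loci$annotation_family[i], loci$phylo_family[i])
    if (!is.na(loci$host_transcript[i]))
      a <- paste0(a, ";host_transcript=", loci$host_transcript[i])
    if (!is.na(loci$ortholog_group[i]) &&
        loci$ortholog_group[i] != loci$phylo_family[i])
      a <- paste0(a, ";ortholog_group=", loci$ortholog_group[i])
    a
  }
  body <- vapply(seq_len(nrow(loci)), function(i) {
    paste(loci$chrom[i], ".", GFF3_PRECURSOR_TYPE, loci$start[i], loci$end[i],
          ".", loci$strand[i], ".", attr_of(i), sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export clusters as BED6
#'
#' One BED record per cluster spanning from the first member's start to the
#' last member's end. GFF3 1-based inclusive coordinates are converted to
#' BED 0-based half-open. Score is the member count.
#'
#' @param clusters A cluster table from [call_clusters()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  lines <- vapply(seq_len(nrow(clusters)), function(i) {
    paste(clusters$chrom[i], clusters$start[i] - 1L, clusters$end[i],
          clusters$cluster_id[i], clusters$n_members[i], clusters$strand[i],
          sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a read-count matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of microRNA
#' identifiers; cells are non-negative read counts.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix, rows = microRNAs, columns = samples.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  validate_expression_matrix(m)
}

#' Validate an expression matrix
#'
#' @param m Numeric matrix, rows = microRNAs, columns = samples.
#' @return `m`, after checking non-negativity and unique dimnames.
#' @export
validate_expression_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have row and column names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("expression matrix dimnames must be unique")
  if (any(m < 0, na.rm = TRUE)) stop("expression counts must be >= 0")
  m
}

#' Write a read-count matrix as TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(mirna_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
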