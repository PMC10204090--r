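#' Read a genome annotation feature table
#'
#' Parses the NCBI-assembly-style tab-delimited `*_feature_table.txt` dialect.
#' Only CDS rows are retained; a leading `"# feature"` header marker is
#' tolerated. Rows lacking a locus tag are dropped (count logged). Features
#' are sorted by start coordinate within each replicon and assigned a dense
#' 0-based gene index per replicon -- the coordinate system the operon and
#' regulator proximity rules operate in.
#'
#' @param path path to the feature table file.
#' @param organism_code optional organism code attached as an attribute.
#' @param assembly_accession optional assembly accession attached as an
#'   attribute.
#' @return tibble with columns `genomic_accession`, `start`, `end`, `strand`,
#'   `locus_tag`, `annotation`, `index`; attributes `organism_code` and
#'   `assembly_accession`. Coordinates are 1-based inclusive; strands are
#'   `"+"`/`"-"` (a Unicode minus on input is accepted).
#' @export
read_feature_table <- function(path, organism_code = NA_character_,
                               assembly_accession = NA_character_) {
  header <- readr::read_lines(path, n_max = 1)
  lines <- readr::read_lines(path)
  lines[1] <- sub("^#\\s*", "", header)
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("feature", "genomic_accession", "start", "end", "strand",
                "locus_tag", "name")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("feature table ", path, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  cds <- df |>
    filter(feature == "CDS") |>
    select(genomic_accession, start, end, strand, locus_tag, annotation = name)
  n_no_tag <- sum(is.na(cds$locus_tag) | !nzchar(trimws(cds$locus_tag)))
  if (n_no_tag > 0) {
    inform(sprintf("%s: dropped %d CDS row(s) lacking a locus_tag", path, n_no_tag))
    cds <- filter(cds, !is.na(locus_tag) & nzchar(trimws(locus_tag)))
  }
  cds <- cds |>
    mutate(
      start = as.integer(start),
      end = as.integer(end),
      strand = normalise_strand(strand),
      annotation = ifelse(is.na(annotation), "", annotation)
    )
  new_feature_table(cds, organism_code = organism_code,
                    assembly_accession = assembly_accession)
}

#' Assemble a feature table from a tibble of CDS features
#'
#' Validates, sorts and indexes a feature tibble the same way
#' [read_feature_table()] does for files. Used by the genome simulator and
#' available for building tables in code.
#'
#' @param features tibble with columns `genomic_accession`, `start`, `end`,
#'   `strand`, `locus_tag`, `annotation`.
#' @param organism_code,assembly_accession attached as attributes.
#' @return indexed feature tibble (see [read_feature_table()]).
#' @export
new_feature_table <- function(features, organism_code = NA_character_,
                              assembly_accession = NA_character_) {
  features <- as_tibble(features)
  stopifnot(all(c("genomic_accession", "start", "end", "strand",
                  "locus_tag", "annotation") %in% names(features)))
  if (any(features$start < 1)) abort("feature start coordinates must be >= 1")
  if (any(features$end < features$start)) abort("feature end must be >= start")
  features$strand <- normalise_strand(features$strand)
  dup <- features$locus_tag[duplicated(features$locus_tag)]
  if (length(dup) > 0) {
    abort(paste0("duplicate locus_tag(s) in feature table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  out <- features |>
    arrange(genomic_accession, start) |>
    group_by(genomic_accession) |>
    mutate(index = row_number() - 1L) |>
    ungroup()
  attr(out, "organism_code") <- organism_code
  attr(out, "assembly_accession") <- assembly_accession
  out
}

normalise_strand <- function(x) {
  x <- gsub("−", "-", x)
  if (!all(x %in% c("+", "-"))) {
    abort("strand values must be '+' or '-'")
  }
  x
}

#' Write a feature table in the NCBI-assembly-style dialect
#'
#' @param features an indexed feature tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features |>
    mutate(feature = "CDS", class = "with_protein", .before = 1) |>
    select(feature, class, genomic_accession, start, end, strand,
           locus_tag, name = annotation)
  txt <- readr::format_tsv(out)
  txt <- sub("^feature", "# feature", txt)
  readr::write_lines(txt, path, sep = "")
  invisible(path)
}

#' Map per-step gene ids onto a genome's features
#'
#' Matches the gene ids proposed for each chain step against the feature
#' table's locus tags (case-insensitive exact match) and enumerates candidate
#' member assignments, one feature per step. When a step's gene has several
#' genomic copies the combinations are enumerated, ordered by genomic span
#' ascending (assignments spread over several replicons sort last) and capped.
#'
#' @param features an indexed feature tibble.
#' @param per_step_genes list of character vectors: candidate gene ids for
#'   each chain step, in step order.
#' @param combination_cap maximum number of assignments returned (default
#'   50); exceeding it keeps the tightest-span assignments with a warning.
#' @return tibble with one row per assignment: `assignment` (integer id),
#'   `span` (bp; `Inf` across replicons) and `members`, a list-column of
#'   feature tibbles carrying a `step` column. Zero rows if any step has no
#'   matching locus tag.
#' @export
locate_chain_genes <- function(features, per_step_genes, combination_cap = 50) {
  stopifnot(is.list(per_step_genes), length(per_step_genes) >= 1)
  tags_lower <- tolower(features$locus_tag)
  per_step_rows <- purrr::map(per_step_genes, function(genes) {
    which(tags_lower %in% tolower(genes))
  })
  if (any(lengths(per_step_rows) == 0)) {
    return(tibble(assignment = integer(), span = double(), members = list()))
  }
  combos <- expand.grid(per_step_rows, KEEP.OUT.ATTRS = FALSE)
  n_total <- nrow(combos)
  members <- purrr::map(seq_len(n_total), function(i) {
    rows <- as.integer(combos[i, ])
    mutate(features[rows, ], step = seq_along(rows))
  })
  spans <- map_dbl(members, function(m) {
    if (length(unique(m$genomic_accession)) > 1) Inf else max(m$end) - min(m$start)
  })
  ord <- order(spans)
  members <- members[ord]
  spans <- spans[ord]
  if (n_total > combination_cap) {
    warn(sprintf("gene-copy combinations (%d) exceed cap (%d); keeping tightest spans",
                 n_total, combination_cap))
    members <- members[seq_len(combination_cap)]
    spans <- spans[seq_len(combination_cap)]
  }
  tibble(assignment = seq_along(members), span = spans, members = members)
}
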