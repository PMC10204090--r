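#' Construct a reaction knowledge base
#'
#' A knowledge base houses the three tables the mining pipeline queries:
#' compounds, directed enzymatic reactions, and enzyme-to-gene links per
#' organism. It is the in-memory equivalent of a local snapshot of the
#' compound/reaction/enzyme sub-databases a practitioner would otherwise
#' query over REST.
#'
#' @param compounds tibble with columns `compound_id`, `name`.
#' @param reactions tibble with columns `reaction_id`, `equation` (written
#'   direction, sides separated by `"<=>"`), and `ec_numbers`
#'   (semicolon-joined EC strings; partial ECs such as `"1.1.1.-"` allowed).
#' @param enzymes tibble with columns `ec`, `organism` (lowercase 3-4 letter
#'   organism code) and `genes` (space-joined gene/locus identifiers), one row
#'   per ec-organism pair.
#'
#' @return An object of class `tfb_kb`: a list of normalised tibbles
#'   (`compounds`, `reactions`, `enzymes`, and a long `participants` index
#'   with one row per reaction-side-compound).
#' @export
kb_new <- function(compounds = NULL, reactions = NULL, enzymes = NULL) {
  compounds <- if (is.null(compounds)) {
    tibble(compound_id = character(), name = character())
  } else {
    as_tibble(compounds)[, c("compound_id", "name")]
  }
  reactions <- if (is.null(reactions)) {
    tibble(reaction_id = character(), equation = character(),
           ec_numbers = character())
  } else {
    as_tibble(reactions)[, c("reaction_id", "equation", "ec_numbers")]
  }
  enzymes <- if (is.null(enzymes)) {
    tibble(ec = character(), organism = character(), genes = character())
  } else {
    as_tibble(enzymes)[, c("ec", "organism", "genes")]
  }

  dup <- reactions$reaction_id[duplicated(reactions$reaction_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate reaction id(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_genes <- enzymes$genes[!nzchar(trimws(enzymes$genes))]
  if (length(bad_genes) > 0 || anyNA(enzymes$genes)) {
    abort("every enzyme ec-organism row must list at least one gene")
  }

  participants <- if (nrow(reactions) > 0) {
    purrr::map2(reactions$reaction_id, reactions$equation, function(rid, eq) {
      sides <- parse_reaction_equation(eq)
      bind_rows(
        mutate(sides$substrates, side = "substrate"),
        mutate(sides$products, side = "product")
      ) |>
        mutate(reaction_id = rid)
    }) |>
      list_rbind() |>
      select(reaction_id, compound_id, coef, side)
  } else {
    tibble(reaction_id = character(), compound_id = character(),
           coef = integer(), side = character())
  }

  structure(
    list(compounds = compounds, reactions = reactions, enzymes = enzymes,
         participants = participants),
    class = "tfb_kb"
  )
}

#' @export
print.tfb_kb <- function(x, ...) {
  cat(sprintf(
    "<tfb_kb> %d compounds, %d reactions, %d ec-organism gene links\n",
    nrow(x$compounds), nrow(x$reactions), nrow(x$enzymes)
  ))
  invisible(x)
}

#' Parse a reaction equation string
#'
#' Parses the flat-file equation dialect: terms joined by `" + "`, the two
#' sides separated by a single `"<=>"`, each term an optional integer
#' stoichiometric coefficient followed by a compound id. Compounds without an
#' explicit coefficient get coefficient 1.
#'
#' @param text equation string, e.g. `"2 C00001 + C90001 <=> C90002"`.
#' @return list with tibbles `substrates` and `products`, each with columns
#'   `compound_id` and `coef`.
#' @examples
#' parse_reaction_equation("C02479 <=> C00508")
#' @export
parse_reaction_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n_sep <- stringr::str_count(text, stringr::fixed("<=>"))
  if (n_sep != 1) {
    abort(paste0("equation must contain exactly one '<=>' separator: ", text))
  }
  sides <- stringr::str_split_fixed(text, stringr::fixed("<=>"), 2)
  parse_side <- function(side_text, label) {
    side_text <- trimws(side_text)
    if (!nzchar(side_text)) {
      abort(paste0("empty ", label, " side in equation: ", text))
    }
    terms <- trimws(stringr::str_split_1(side_text, stringr::fixed(" + ")))
    parsed <- purrr::map(terms, function(term) {
      m <- stringr::str_match(term, "^(?:(\\d+)\\s+)?(\\S+)$")
      if (is.na(m[1, 1])) {
        abort(paste0("malformed equation term '", term, "' in: ", text))
      }
      tibble(
        compound_id = m[1, 3],
        coef = if (is.na(m[1, 2])) 1L else as.integer(m[1, 2])
      )
    })
    list_rbind(parsed)
  }
  list(
    substrates = parse_side(sides[1, 1], "substrate"),
    products   = parse_side(sides[1, 2], "product")
  )
}

#' Reactions involving a compound (either side)
#'
#' @param kb a `tfb_kb`.
#' @param compound compound id.
#' @return character vector of reaction ids.
#' @export
reactions_for_compound <- function(kb, compound) {
  stopifnot(inherits(kb, "tfb_kb"))
  sort(unique(kb$participants$reaction_id[kb$participants$compound_id == compound]))
}

#' Reactions that consume a compound
#'
#' Returns exactly the reactions in which the compound appears on the
#' substrate (left) side as written. Reactions listing the compound only as a
#' product are excluded: traversal honours the written direction, which is
#' what makes the search miss compounds that the knowledge base only ever
#' writes as products (a documented behaviour of this style of mining, e.g.
#' for R-mandelate, which is listed only as the product of a racemase).
#'
#' @param kb a `tfb_kb`.
#' @param compound compound id. Unknown compounds yield an empty result with
#'   a logged notice, not an error: absent biology is "no chains", not
#'   broken input.
#' @param treat_reversible also return reactions where the compound appears
#'   on the product side, reoriented right-to-left (default `FALSE`).
#' @return tibble with columns `reaction_id`, `ec_numbers`, `substrates`,
#'   `products` (list-columns of compound/coef tibbles, in traversal
#'   orientation) and `both_sides` (flag: the compound appears verbatim on
#'   both sides of the written equation).
#' @export
reactions_consuming <- function(kb, compound, treat_reversible = FALSE) {
  stopifnot(inherits(kb, "tfb_kb"))
  part <- kb$participants[kb$participants$compound_id == compound, ]
  if (nrow(part) == 0) {
    inform(paste0("compound ", compound, " not found in knowledge base; no reactions"))
    return(tibble(reaction_id = character(), ec_numbers = list(),
                  substrates = list(), products = list(),
                  both_sides = logical(), reversed = logical()))
  }
  as_sub <- unique(part$reaction_id[part$side == "substrate"])
  as_prod <- unique(part$reaction_id[part$side == "product"])

  orient <- function(rids, reversed) {
    if (length(rids) == 0) return(NULL)
    rows <- kb$reactions[match(rids, kb$reactions$reaction_id), ]
    sides <- purrr::map(rows$equation, parse_reaction_equation)
    tibble(
      reaction_id = rows$reaction_id,
      ec_numbers = purrr::map(rows$ec_numbers, split_semicolon),
      substrates = purrr::map(sides, if (reversed) "products" else "substrates"),
      products   = purrr::map(sides, if (reversed) "substrates" else "products"),
      both_sides = rows$reaction_id %in% intersect(as_sub, as_prod),
      reversed = reversed
    )
  }

  out <- orient(sort(as_sub), reversed = FALSE)
  if (treat_reversible) {
    rev_only <- sort(setdiff(as_prod, as_sub))
    out <- bind_rows(out, orient(rev_only, reversed = TRUE))
  }
  if (is.null(out)) {
    out <- tibble(reaction_id = character(), ec_numbers = list(),
                  substrates = list(), products = list(),
                  both_sides = logical(), reversed = logical())
  }
  if (any(out$both_sides)) {
    inform(paste0(
      "compound ", compound, " appears on both sides of: ",
      paste(out$reaction_id[out$both_sides], collapse = ", ")
    ))
  }
  arrange(out, reaction_id)
}

#' Gene links for an EC number
#'
#' @param kb a `tfb_kb`.
#' @param ec EC number string.
#' @return tibble with columns `organism` and `genes` (list-column of gene id
#'   character vectors); zero rows if the EC is unknown.
#' @export
genes_for_ec <- function(kb, ec) {
  stopifnot(inherits(kb, "tfb_kb"))
  rows <- kb$enzymes[kb$enzymes$ec == ec, ]
  # several rows for one organism (e.g. paralogous copies recorded
  # separately) merge into one entry with the union of gene ids
  tibble(
    organism = rows$organism,
    gene = purrr::map(rows$genes, function(g) strsplit(trimws(g), "\\s+")[[1]])
  ) |>
    tidyr::unnest(gene) |>
    distinct(organism, gene) |>
    group_by(organism) |>
    summarise(genes = list(gene)) |>
    arrange(organism)
}

split_semicolon <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Load a knowledge-base snapshot from flat files
#'
#' Reads the three-file dump dialect: `compounds.tsv` (compound_id, name,
#' semicolon-joined reaction_ids), `reactions.tsv` (reaction_id, equation,
#' semicolon-joined ec_numbers) and `enzymes.tsv` (ec, organism, space-joined
#' genes; one row per ec-organism pair). All are UTF-8 TSV with a header row.
#'
#' @param dir_path directory containing the three files.
#' @return a `tfb_kb`.
#' @export
read_kb <- function(dir_path) {
  needed <- c("compounds.tsv", "reactions.tsv", "enzymes.tsv")
  paths <- file.path(dir_path, needed)
  missing <- needed[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0("knowledge-base dump is missing file(s): ",
                 paste(missing, collapse = ", "), " in ", dir_path))
  }
  read1 <- function(p, cols) {
    df <- readr::read_tsv(p, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(paste0(basename(p), " is missing column(s): ", paste(miss, collapse = ", ")))
    }
    df
  }
  compounds <- read1(paths[1], c("compound_id", "name"))
  reactions <- read1(paths[2], c("reaction_id", "equation", "ec_numbers"))
  enzymes <- read1(paths[3], c("ec", "organism", "genes"))
  dup <- reactions$reaction_id[duplicated(reactions$reaction_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate reaction id(s) in ", paths[2], ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  kb <- kb_new(compounds = compounds, reactions = reactions, enzymes = enzymes)
  inform(sprintf("loaded knowledge base: %d compounds, %d reactions, %d enzyme links",
                 nrow(kb$compounds), nrow(kb$reactions), nrow(kb$enzymes)))
  kb
}

#' Write a knowledge base to the flat-file dump dialect
#'
#' Inverse of [read_kb()]: reloading the written directory yields identical
#' lookup results for every compound and EC.
#'
#' @param kb a `tfb_kb`.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_kb <- function(kb, dir_path) {
  stopifnot(inherits(kb, "tfb_kb"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  link <- kb$participants |>
    group_by(compound_id) |>
    summarise(reaction_ids = paste(sort(unique(reaction_id)), collapse = ";"))
  compounds <- left_join(kb$compounds, link, by = "compound_id") |>
    mutate(reaction_ids = ifelse(is.na(reaction_ids), "", reaction_ids))
  readr::write_tsv(compounds, file.path(dir_path, "compounds.tsv"), progress = FALSE)
  readr::write_tsv(kb$reactions, file.path(dir_path, "reactions.tsv"), progress = FALSE)
  readr::write_tsv(kb$enzymes, file.path(dir_path, "enzymes.tsv"), progress = FALSE)
  invisible(dir_path)
}
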