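#' The beta-L-arabinose worked-example knowledge base
#'
#' Builds the four-reaction knowledge base of the canonical arabinose
#' utilisation route: L-arabinose isomerase (EC 5.3.1.4) converts
#' beta-L-arabinose (C02479) to L-ribulose; ribulokinase (EC 2.7.1.16)
#' phosphorylates it to L-ribulose 5-phosphate; from there either
#' L-ribulose-5-phosphate 4-epimerase (EC 5.1.3.4) or
#' L-ribulose-5-phosphate 3-epimerase (EC 5.1.3.22) yields a xylulose
#' 5-phosphate isomer. Enumerating chains from C02479 at maximum length 3
#' yields three chains: one of length 2 and two of length 3.
#'
#' Intermediate compound ids follow the standard compound-id convention;
#' reaction ids are synthetic (R9xxxx) fixture codes.
#'
#' @param enzyme_links optional tibble with columns `ec`, `organism`, `genes`
#'   (space-joined gene ids) linking the four ECs to organisms, e.g. as
#'   produced by [simulate_genome()]; default none.
#' @return a `tfb_kb` with 6 compounds and 4 reactions.
#' @export
arabinose_kb <- function(enzyme_links = NULL) {
  compounds <- tibble(
    compound_id = c("C02479", "C00508", "C01101", "C00231", "C03291"),
    name = c("beta-L-arabinose", "L-ribulose", "L-ribulose 5-phosphate",
             "D-xylulose 5-phosphate", "L-xylulose 5-phosphate")
  )
  reactions <- tibble(
    reaction_id = c("R90001", "R90002", "R90003", "R90004"),
    equation = c(
      "C02479 <=> C00508",
      "C00508 <=> C01101",
      "C01101 <=> C00231",
      "C01101 <=> C03291"
    ),
    ec_numbers = c("5.3.1.4", "2.7.1.16", "5.1.3.4", "5.1.3.22")
  )
  enzymes <- if (is.null(enzyme_links)) {
    tibble(ec = character(), organism = character(), genes = character())
  } else {
    as_tibble(enzyme_links)
  }
  kb_new(compounds = compounds, reactions = reactions, enzymes = enzymes)
}

# keyword-free decoy annotations: false-positive regulator hits are
# impossible by construction in negative-control genomes
decoy_annotation_pool <- function() {
  c("benzaldehyde dehydrogenase", "ABC transporter permease",
    "aldolase class II", "glucokinase", "enoyl-CoA hydratase",
    "acyl carrier protein", "phosphoglycerate mutase",
    "cytochrome c oxidase subunit II", "ribosomal protein L31",
    "MFS transporter", "aminotransferase class I",
    "shikimate dehydrogenase", "outer membrane porin",
    "thioredoxin reductase", "polyphosphate kinase")
}

# adversarial pool: decoys whose annotations do contain regulator keywords,
# for stress-testing keyword screens
adversarial_annotation_pool <- function() {
  c("two-component response regulator", "transcriptional activator homolog",
    "putative repressor protein", "sigma factor regulator fragment")
}

#' Specify a synthetic genome with planted operon-regulator arrangements
#'
#' @param organism_code lowercase organism code (3-4 letters).
#' @param n_genes total number of CDS features on the single replicon.
#' @param operons list of planted operons, each a list with fields `ecs`
#'   (character vector, chain-step order), `start_index` (0-based gene index
#'   of the first member in genomic order), `strand` (`"+"`/`"-"`) and
#'   optionally `gaps` (integer vector, length `length(ecs) - 1`: intervening
#'   decoy genes between consecutive members; default all 0).
#' @param regulators list parallel to `operons` (or shorter), each a list
#'   with `offset` (genes strictly between the regulator and the operon's 5'
#'   member), `strand` (must differ from the operon's to be divergent),
#'   `annotation` (free text) and optionally `between_strands` (strand of
#'   each of the `offset` intervening decoys; default: all on the operon
#'   strand).
#' @param decoy_pool annotation vocabulary for filler genes (default
#'   keyword-free; see [default_regulator_keywords()]).
#' @param seed integer seed controlling coordinates and decoy draw.
#' @param assembly_accession,replicon identifiers used in the emitted table.
#' @return a `genome_spec` list, validated for feasibility.
#' @export
genome_spec <- function(organism_code, n_genes = 60, operons = list(),
                        regulators = list(),
                        decoy_pool = decoy_annotation_pool(),
                        seed = 1,
                        assembly_accession = paste0("GCA_SYN_", organism_code),
                        replicon = paste0("SYN_", toupper(organism_code), "_1")) {
  spec <- list(
    organism_code = organism_code, n_genes = as.integer(n_genes),
    operons = operons, regulators = regulators, decoy_pool = decoy_pool,
    seed = as.integer(seed), assembly_accession = assembly_accession,
    replicon = replicon
  )
  class(spec) <- "genome_spec"
  validate_genome_spec(spec)
  spec
}

validate_genome_spec <- function(spec) {
  claimed <- integer()
  for (i in seq_along(spec$operons)) {
    op <- spec$operons[[i]]
    stopifnot(is.character(op$ecs), length(op$ecs) >= 1,
              op$strand %in% c("+", "-"))
    gaps <- op$gaps %||% rep(0L, length(op$ecs) - 1)
    if (length(op$ecs) > 1 && length(gaps) != length(op$ecs) - 1) {
      abort(sprintf("operon %d: gaps must have length(ecs) - 1 entries", i))
    }
    member_idx <- planted_member_indices(op$start_index, gaps)
    idx <- seq(op$start_index, max(member_idx))
    reg <- if (i <= length(spec$regulators)) spec$regulators[[i]] else NULL
    if (!is.null(reg)) {
      upstream_member <- if (op$strand == "+") min(member_idx) else max(member_idx)
      dir <- if (op$strand == "+") -1L else 1L
      reg_idx <- upstream_member + dir * (reg$offset + 1L)
      idx <- c(idx, seq(min(upstream_member, reg_idx), max(upstream_member, reg_idx)))
    }
    if (min(idx) < 0 || max(idx) >= spec$n_genes) {
      abort(sprintf("operon/regulator %d does not fit within n_genes = %d", i, spec$n_genes))
    }
    if (any(idx %in% claimed)) {
      abort(sprintf("planted elements overlap at operon %d", i))
    }
    claimed <- c(claimed, idx)
  }
  invisible(spec)
}

planted_member_indices <- function(start_index, gaps) {
  idx <- as.integer(start_index)
  for (g in gaps) idx <- c(idx, idx[length(idx)] + g + 1L)
  idx
}

#' Simulate an annotated genome with planted biosensor arrangements
#'
#' Generates a deterministic (per seed) single-replicon feature table with
#' non-overlapping 1-based gene coordinates, plants the operons and divergent
#' regulators described in the spec, fills the remaining positions with
#' decoy genes, and returns a truth table holding each planted candidate's
#' expected proximity score, computed directly from the spec by the scoring
#' formula (one point per intervening operon-strand gene, two per
#' regulator-strand gene, clamped at -500). Changing the seed changes
#' coordinates and decoy annotations but never the truth scores.
#'
#' @param spec a [genome_spec()].
#' @return list with `features` (indexed feature tibble), `truth` (tibble:
#'   one row per planted operon with `member_tags`, `regulator_tag`,
#'   `expected_score`), and `gene_map` (tibble `ec`, `organism`, `genes`
#'   ready for [arabinose_kb()]'s `enzyme_links` or [kb_new()]).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  rng <- local_rng(spec$seed)
  n <- spec$n_genes
  lens <- rng$integer(n, 300, 2500)
  gaps_bp <- rng$integer(n, 20, 200)
  starts <- cumsum(c(1L, head(lens + gaps_bp, -1)))
  ends <- starts + lens - 1L

  strands <- c("+", "-")[rng$integer(n, 1, 2)]
  annots <- spec$decoy_pool[rng$integer(n, 1, length(spec$decoy_pool))]
  tags <- sprintf("%s_%05d", toupper(spec$organism_code), seq_len(n) * 5L)

  truth_rows <- list()
  gene_map_rows <- list()
  for (i in seq_along(spec$operons)) {
    op <- spec$operons[[i]]
    gaps <- op$gaps %||% rep(0L, length(op$ecs) - 1)
    member_idx <- planted_member_indices(op$start_index, gaps)
    pos <- member_idx + 1L                       # 0-based index -> row
    strands[pos] <- op$strand
    annots[pos] <- paste0(op$ecs, " catabolic enzyme")
    # gap fillers between members sit on the operon strand, keyword-free
    filler <- setdiff(seq(min(member_idx), max(member_idx)), member_idx) + 1L
    strands[filler] <- op$strand

    # chain-step order along the strand: 5' to 3'
    step_order_pos <- if (op$strand == "+") pos else rev(pos)
    gene_map_rows[[i]] <- tibble(
      ec = op$ecs, organism = spec$organism_code, genes = tags[step_order_pos]
    )

    reg <- if (i <= length(spec$regulators)) spec$regulators[[i]] else NULL
    reg_tag <- NA_character_
    expected <- NA_integer_
    if (!is.null(reg)) {
      upstream_member <- if (op$strand == "+") min(member_idx) else max(member_idx)
      dir <- if (op$strand == "+") -1L else 1L
      reg_idx <- upstream_member + dir * (reg$offset + 1L)
      reg_pos <- reg_idx + 1L
      strands[reg_pos] <- reg$strand
      annots[reg_pos] <- reg$annotation
      reg_tag <- tags[reg_pos]
      between_strands <- reg$between_strands %||% rep(op$strand, reg$offset)
      stopifnot(length(between_strands) == reg$offset)
      if (reg$offset > 0) {
        between_idx <- upstream_member + dir * seq_len(reg$offset)
        strands[between_idx + 1L] <- between_strands
      }
      # truth score straight from the spec, independent of the screen
      expected <- max(-500L,
                      -sum(ifelse(between_strands == op$strand, 1L, 2L)))
    }
    truth_rows[[i]] <- tibble(
      operon = i,
      member_tags = paste(tags[sort(pos)], collapse = ";"),
      upstream_tag = tags[(if (op$strand == "+") min(member_idx) else max(member_idx)) + 1L],
      regulator_tag = reg_tag,
      expected_score = expected
    )
  }

  features <- new_feature_table(
    tibble(
      genomic_accession = spec$replicon,
      start = starts, end = ends, strand = strands,
      locus_tag = tags, annotation = annots
    ),
    organism_code = spec$organism_code,
    assembly_accession = spec$assembly_accession
  )
  empty_truth <- tibble(operon = integer(), member_tags = character(),
                        upstream_tag = character(), regulator_tag = character(),
                        expected_score = integer())
  empty_map <- tibble(ec = character(), organism = character(), genes = character())
  list(
    features = features,
    truth = if (length(truth_rows)) list_rbind(truth_rows) else empty_truth,
    gene_map = if (length(gene_map_rows)) list_rbind(gene_map_rows) else empty_map
  )
}

# seed-scoped RNG helper: keeps simulator draws deterministic without
# touching the caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(
    integer = function(n, lo, hi) draw(function() sample(seq.int(lo, hi), n, replace = TRUE)),
    lnorm = function(n, meanlog, sdlog) draw(function() stats::rlnorm(n, meanlog, sdlog))
  )
}

#' Simulate dose-response measurements from a Hill curve
#'
#' Draws replicate fluorescence/optical-density readings whose normalised
#' response lies on the given Hill curve, corrupted by multiplicative
#' log-normal noise with the stated coefficient of variation (mean 1, so the
#' expected response stays on the curve). Raw plate-reader columns
#' (fluorescence, od, blanks) are emitted so the normalisation step is
#' exercised end to end.
#'
#' @param b0,bmax,km,h Hill parameters (basal response, maximal response,
#'   half-maximal concentration in uM, Hill coefficient).
#' @param doses inducer concentrations (uM); 0 represents uninduced wells.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param n_reps replicates per dose (default 3).
#' @param seed integer seed.
#' @param od,od_blank,fluorescence_blank plate constants used to back out raw
#'   readings from the noisy normalised response.
#' @return tibble with columns `inducer_conc_uM`, `replicate`,
#'   `fluorescence`, `od`, `fluorescence_blank`, `od_blank`.
#' @export
simulate_dose_response <- function(b0, bmax, km, h, doses, noise_cv = 0,
                                   n_reps = 3, seed = 1,
                                   od = 0.5, od_blank = 0.05,
                                   fluorescence_blank = 100) {
  stopifnot(noise_cv >= 0, n_reps >= 1)
  rng <- local_rng(seed)
  grid <- tidyr::expand_grid(inducer_conc_uM = doses, replicate = seq_len(n_reps))
  mu <- hill_response(grid$inducer_conc_uM, b0 = b0, bmax = bmax, km = km, h = h)
  noise <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rng$lnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, nrow(grid))
  }
  response <- mu * noise
  grid |>
    mutate(
      fluorescence = response * (od - od_blank) + fluorescence_blank,
      od = od, fluorescence_blank = fluorescence_blank, od_blank = od_blank
    )
}
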