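#' Default rooted species tree of the eight studied Archamoebae
#'
#' The working topology: Entamoebidae branches first, Rhizomastixidae is
#' sister to a clade in which Pelomyxidae and Mastigamoebidae are sisters.
#' `alt_species_tree()` returns the competing published placement in which
#' Rhizomastixidae is sister to Pelomyxidae.
#'
#' @return an `ape::phylo` tree with deterministic internal node labels.
#' @export
default_species_tree <- function() {
  parse_newick(paste0(
    "(Entamoeba_histolytica,((Rhizomastix_libera,Rhizomastix_vacuolata),",
    "((Pelomyxa_schiedti,Mastigella_eilhardi),",
    "(Mastigamoeba_balamuthi,(Mastigamoeba_abducta,Endolimax_sp)))));"))
}

#' @rdname default_species_tree
#' @export
alt_species_tree <- function() {
  parse_newick(paste0(
    "(Entamoeba_histolytica,(((Rhizomastix_libera,Rhizomastix_vacuolata),",
    "(Pelomyxa_schiedti,Mastigella_eilhardi)),",
    "(Mastigamoeba_balamuthi,(Mastigamoeba_abducta,Endolimax_sp))));"))
}

# benchmark-like error profiles of the three selected predictors
default_tool_errors <- function() {
  list(
    TargetP2 = list(sensitivity = 0.46, fpr = 0.0012, has_nonplant_mode = TRUE),
    PProwler = list(sensitivity = 0.45, fpr = 0.0100, has_nonplant_mode = TRUE),
    DeepLoc2 = list(sensitivity = 0.77, fpr = 0.0006, has_nonplant_mode = FALSE))
}

#' Configuration of the synthetic-data generator
#'
#' One seeded configuration drives every generator so that identical
#' configurations yield identical outputs.  Default scales mirror the study:
#' 8 species, a reference set of 65 MRO and 800 cytosolic proteins, three
#' selected predictors with benchmark-like sensitivities (0.46/0.45/0.77)
#' and rare false positives, 10 % planted contaminants whose non-target
#' hits clear the decontamination thresholds, and 200 binary characters
#' evolved under single gain plus per-branch loss on the species tree.
#'
#' @param seed integer master seed.
#' @param n_species number of species (leaves of `tree`).
#' @param n_genuine,n_contaminant genuine and planted-contaminant
#'   transcript counts (default 450/50, i.e. 10 % contamination).
#' @param round2_fraction fraction of contaminants detectable only at the
#'   protein level (round 2).
#' @param contaminant_identity,contaminant_coverage `c(mean, sd)` percent of
#'   the planted non-target hits' identity/coverage; identities are
#'   truncated above the relevant round's threshold so planted hits qualify.
#' @param per_tool_error named list: per tool `list(sensitivity, fpr,
#'   has_nonplant_mode)`.
#' @param pt_rate probability that a positive call from a tool without a
#'   non-plant mode is emitted with the raw label `"Plastid"`.
#' @param n_mro_refs,n_cyto_refs reference-set sizes.
#' @param tree rooted species tree (`phylo` or newick string).
#' @param per_branch_loss_prob loss probability per branch below a gain.
#' @param n_characters number of simulated binary characters.
#' @param n_ogs,og_size_range,universe_size,mro_fraction,enriched_fraction,
#'   enrichment_odds orthogroup-generator scales.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 8L,
                       n_genuine = 450L, n_contaminant = 50L,
                       round2_fraction = 0.2,
                       contaminant_identity = c(mean = 85, sd = 5),
                       contaminant_coverage = c(mean = 75, sd = 10),
                       per_tool_error = default_tool_errors(),
                       pt_rate = 0.08,
                       n_mro_refs = 65L, n_cyto_refs = 800L,
                       tree = default_species_tree(),
                       per_branch_loss_prob = 0.1,
                       n_characters = 200L,
                       n_ogs = 100L, og_size_range = c(5L, 40L),
                       universe_size = 5000L, mro_fraction = 0.1,
                       enriched_fraction = 0.1, enrichment_odds = 20) {
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(inherits(tree, "phylo"))
  probs <- c(round2_fraction, pt_rate, per_branch_loss_prob, mro_fraction,
             enriched_fraction,
             unlist(lapply(per_tool_error, function(t)
               c(t$sensitivity, t$fpr))))
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  counts <- c(n_genuine, n_contaminant, n_mro_refs, n_cyto_refs,
              n_characters, n_ogs, universe_size)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (length(tree$tip.label) != n_species)
    stopf("tree has %d leaves but n_species = %d",
          length(tree$tip.label), n_species)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_genuine = as.integer(n_genuine),
                 n_contaminant = as.integer(n_contaminant),
                 round2_fraction = round2_fraction,
                 contaminant_identity = contaminant_identity,
                 contaminant_coverage = contaminant_coverage,
                 per_tool_error = per_tool_error, pt_rate = pt_rate,
                 n_mro_refs = as.integer(n_mro_refs),
                 n_cyto_refs = as.integer(n_cyto_refs),
                 tree = tree,
                 per_branch_loss_prob = per_branch_loss_prob,
                 n_characters = as.integer(n_characters),
                 n_ogs = as.integer(n_ogs),
                 og_size_range = as.integer(og_size_range),
                 universe_size = as.integer(universe_size),
                 mro_fraction = mro_fraction,
                 enriched_fraction = enriched_fraction,
                 enrichment_odds = enrichment_odds),
            class = "sim_config")
}

random_seq <- function(n, len, alphabet) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len, replace = TRUE), collapse = ""), character(1))
}

target_lineage <- "cellular organisms;Eukaryota;Amoebozoa;Archamoebae"
nontarget_lineages <- c(
  "cellular organisms;Bacteria;Pseudomonadota;Gammaproteobacteria",
  "cellular organisms;Bacteria;Bacillota;Clostridia",
  "cellular organisms;Eukaryota;Opisthokonta;Fungi",
  "cellular organisms;Eukaryota;Viridiplantae;Chlorophyta")

make_hits <- function(qseqid, lineage, pident, qcovs, len = 300) {
  n <- length(qseqid)
  if (n == 0L)
    return(read_hit_table(text = character(0), dialect = "outfmt6_tax"))
  data.frame(qseqid = qseqid,
             sseqid = sprintf("subj%05d", seq_len(n)),
             pident = round(pident, 1),
             length = len, mismatch = 0L, gapopen = 0L,
             qstart = 1L, qend = len, sstart = 1L, send = len,
             evalue = signif(10^runif(n, -50, -10), 3),
             bitscore = round(runif(n, 100, 900), 1),
             qcovs = round(qcovs, 0),
             lineage = lineage,
             stringsAsFactors = FALSE)
}

#' Simulate decontamination inputs with planted contaminants
#'
#' Generates an assembly of genuine transcripts (whose hits carry the
#' target-clade lineage) plus planted contaminants whose best hits are
#' non-target with identity/coverage drawn above the round thresholds.
#' A configurable fraction of contaminants is detectable only at the
#' protein level: their nucleotide hits fall below the round-1 identity
#' threshold while their protein hits clear the round-2 threshold.
#' Sequence residues are decorative; all information lives in ids, tables
#' and the ground truth.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   `transcripts.fasta`, `proteins.fasta`, `nt_hits.tsv`, `aa_hits.tsv`
#'   and `truth.json`.
#' @return list with `transcript_ids`, `protein_ids`, `nt_hits`, `aa_hits`,
#'   `transcripts`/`proteins` (named sequences) and `truth` (planted
#'   contaminant ids per round, genuine ids).
#' @export
sim_decontam_inputs <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    n_r2 <- round(config$n_contaminant * config$round2_fraction)
    n_r1 <- config$n_contaminant - n_r2
    genuine <- sprintf("g%04d", seq_len(config$n_genuine))
    contam1 <- if (n_r1) sprintf("c1_%04d", seq_len(n_r1)) else character(0)
    contam2 <- if (n_r2) sprintf("c2_%04d", seq_len(n_r2)) else character(0)
    transcript_ids <- c(genuine, contam1, contam2)
    protein_ids <- paste0(transcript_ids, ".p1")

    ci <- config$contaminant_identity
    cc <- config$contaminant_coverage
    nt_hits <- rbind(
      make_hits(genuine, sample(target_lineage, config$n_genuine, TRUE),
                rnorm_trunc(config$n_genuine, 80, 10, 40, 100),
                rnorm_trunc(config$n_genuine, 70, 15, 20, 100)),
      make_hits(contam1, sample(nontarget_lineages, n_r1, TRUE),
                rnorm_trunc(n_r1, ci["mean"], ci["sd"], 75, 100),
                rnorm_trunc(n_r1, cc["mean"], cc["sd"], 50, 100)),
      # round-2-only contaminants stay under the round-1 identity threshold
      make_hits(contam2, sample(nontarget_lineages, n_r2, TRUE),
                rnorm_trunc(n_r2, 65, 3, 40, 74.9),
                rnorm_trunc(n_r2, cc["mean"], cc["sd"], 50, 100)))
    aa_hits <- rbind(
      make_hits(paste0(genuine, ".p1"),
                sample(target_lineage, config$n_genuine, TRUE),
                rnorm_trunc(config$n_genuine, 75, 10, 40, 100),
                rnorm_trunc(config$n_genuine, 70, 15, 20, 100)),
      make_hits(paste0(contam2, ".p1"),
                sample(nontarget_lineages, n_r2, TRUE),
                rnorm_trunc(n_r2, ci["mean"], ci["sd"], 70, 100),
                rnorm_trunc(n_r2, cc["mean"], cc["sd"], 50, 100)))
    transcripts <- setNames(
      random_seq(length(transcript_ids), 300, c("A", "C", "G", "T")),
      transcript_ids)
    proteins <- setNames(
      random_seq(length(protein_ids), 100, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
      protein_ids)
    truth <- list(contaminant_transcripts_round1 = contam1,
                  contaminant_transcripts_round2 = contam2,
                  contaminant_proteins_round2 = paste0(contam2, ".p1"),
                  genuine_ids = genuine)
    out <- list(transcript_ids = transcript_ids, protein_ids = protein_ids,
                nt_hits = nt_hits, aa_hits = aa_hits,
                transcripts = transcripts, proteins = proteins, truth = truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$transcripts, file.path(dir, "transcripts.fasta"))
    write_fasta(out$proteins, file.path(dir, "proteins.fasta"))
    write_hit_table(out$nt_hits, file.path(dir, "nt_hits.tsv"), "outfmt6_tax")
    write_hit_table(out$aa_hits, file.path(dir, "aa_hits.tsv"), "outfmt6_tax")
    jsonlite::write_json(out$truth, file.path(dir, "truth_decontam.json"))
  }
  out
}

#' Simulate predictor call tables with controlled error rates
#'
#' Each tool calls an MRO-labelled reference positive with probability equal
#' to its configured sensitivity and a cytosolic reference positive with
#' probability equal to its false-positive rate, independently across tools
#' and proteins.  Tools without a non-plant mode emit a fraction of their
#' positive calls with the raw label `"Plastid"`, exercising the PT->MT
#' normalization rule.
#'
#' @param config a [sim_config()].
#' @param labels optional reference labels; generated at the configured
#'   scale when `NULL`.
#' @return list with `calls` (normalized call table), `raw_calls`,
#'   `labels`, `profiles` (per-tool [tool_profile()]s) and `truth` (the
#'   per-tool true rates).
#' @export
sim_predictor_calls <- function(config, labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 202L, {
    if (is.null(labels)) {
      n_rib <- round(config$n_cyto_refs * 0.6)
      labels <- build_reference_labels(
        sprintf("mro%04d", seq_len(config$n_mro_refs)),
        sprintf("rib%04d", seq_len(n_rib)),
        sprintf("rep%04d", seq_len(config$n_cyto_refs - n_rib)))
    }
    profiles <- list()
    raw_all <- list()
    for (tool in names(config$per_tool_error)) {
      err <- config$per_tool_error[[tool]]
      vocab <- c("Mitochondrion", "Other")
      plastid <- character(0)
      if (!isTRUE(err$has_nonplant_mode)) {
        vocab <- c(vocab, "Plastid")
        plastid <- "Plastid"
      }
      profiles[[tool]] <- tool_profile(tool, vocab, "Mitochondrion", plastid,
                                       has_nonplant_mode =
                                         isTRUE(err$has_nonplant_mode))
      p_pos <- ifelse(labels$truth == "MRO", err$sensitivity, err$fpr)
      pos <- runif(nrow(labels)) < p_pos
      raw <- ifelse(pos, "Mitochondrion", "Other")
      if (length(plastid)) {
        as_pt <- pos & runif(nrow(labels)) < config$pt_rate
        raw[as_pt] <- "Plastid"
      }
      raw_all[[tool]] <- data.frame(protein_id = labels$protein_id,
                                    raw_class = raw,
                                    score = round(runif(nrow(labels)), 3),
                                    stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, lapply(names(profiles), function(tool)
      normalize_calls(raw_all[[tool]], profiles[[tool]])))
    rownames(calls) <- NULL
    list(calls = calls, raw_calls = raw_all, labels = labels,
         profiles = profiles,
         truth = config$per_tool_error)
  })
}

#' Simulate a character matrix under single gain and per-branch loss
#'
#' Each character originates once, at a node drawn uniformly over all nodes
#' of the rooted tree, and is subsequently lost on each branch below a
#' still-present lineage with probability `per_branch_loss_prob` (a lost
#' character stays lost).  Leaf states, the true gain node and the realized
#' loss branches are recorded.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (species x character binary matrix), `tree`
#'   and `truth` (per character: `gain_node`, `loss_branches`).
#' @export
sim_character_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$tree
  labels <- node_labels(tree)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  with_seed(config$seed + 303L, {
    chars <- sprintf("ch%03d", seq_len(config$n_characters))
    m <- matrix(0L, ntip, config$n_characters,
                dimnames = list(tree$tip.label, chars))
    truth <- vector("list", config$n_characters)
    names(truth) <- chars
    for (j in seq_len(config$n_characters)) {
      gain <- sample.int(n_nodes, 1)
      st <- integer(n_nodes)
      st[gain] <- 1L
      losses <- character(0)
      for (i in rev(seq_len(nrow(edges)))) {   # preorder
        parent <- edges[i, 1]; child <- edges[i, 2]
        if (child == gain) next
        if (st[parent] == 1L) {
          if (runif(1) < config$per_branch_loss_prob) {
            losses <- c(losses, labels[child])
          } else st[child] <- 1L
        }
      }
      m[, j] <- st[seq_len(ntip)]
      truth[[j]] <- list(gain_node = labels[gain],
                         loss_branches = sort(losses))
    }
    list(matrix = m, tree = tree, truth = truth)
  })
}

#' Simulate orthogroups with planted enrichment
#'
#' Partitions a universe of protein ids into orthogroups.  A configured
#' fraction of groups is enriched: their members are drawn with odds
#' `enrichment_odds` in favour of MRO-predicted proteins; null groups draw
#' uniformly.  With `enrichment_odds = 1` no group is flagged and the
#' generator is an exchangeable null.
#'
#' @param config a [sim_config()].
#' @param mro_ids optional MRO id set; defaults to a random
#'   `mro_fraction` of the universe.
#' @return list with `ogs` (data.frame `og_id`, `member`), `mro_ids`,
#'   `universe` and `truth` (logical `enriched` per group).
#' @export
sim_orthogroups <- function(config, mro_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 404L, {
    universe <- sprintf("p%06d", seq_len(config$universe_size))
    if (is.null(mro_ids))
      mro_ids <- sample(universe, round(config$universe_size *
                                          config$mro_fraction))
    sizes <- sample(seq(config$og_size_range[1], config$og_size_range[2]),
                    config$n_ogs, replace = TRUE)
    if (sum(sizes) > length(universe))
      stopf("orthogroup sizes exceed the universe; enlarge universe_size")
    odds <- config$enrichment_odds
    n_enriched <- if (odds > 1) round(config$n_ogs * config$enriched_fraction)
                  else 0L
    enriched <- seq_len(config$n_ogs) <= n_enriched
    pool <- universe
    is_mro <- pool %in% mro_ids
    members <- vector("list", config$n_ogs)
    for (i in seq_len(config$n_ogs)) {
      w <- if (enriched[i]) ifelse(is_mro, odds, 1) else rep(1, length(pool))
      pick <- sample.int(length(pool), sizes[i], prob = w)
      members[[i]] <- sort(pool[pick])
      keep <- setdiff(seq_along(pool), pick)
      pool <- pool[keep]; is_mro <- is_mro[keep]
    }
    ogs <- data.frame(og_id = rep(sprintf("OG%07d", seq_len(config$n_ogs)),
                                  lengths(members)),
                      member = unlist(members), stringsAsFactors = FALSE)
    list(ogs = ogs, mro_ids = mro_ids, universe = universe,
         truth = data.frame(og_id = sprintf("OG%07d", seq_len(config$n_ogs)),
                            enriched = enriched, stringsAsFactors = FALSE))
  })
}

#' Minimal FASTA writer/reader for the synthetic fixtures
#'
#' Thin wrappers over `Biostrings` when it is installed, with a plain-text
#' fallback; the pipeline only ever uses FASTA for sequence ids.
#'
#' @param seqs named character vector of sequences.
#' @param file path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(seqs, file) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), file)
  } else {
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), file)
  }
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(file)
    setNames(as.character(x), names(x))
  } else {
    lines <- readLines(file)
    hdr <- grepl("^>", lines)
    ids <- sub("^>", "", lines[hdr])
    grp <- cumsum(hdr)
    setNames(vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                    collapse = ""), ids)
  }
}
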