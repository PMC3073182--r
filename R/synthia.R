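# Synthetic scenario generator: builds all four pipeline inputs (rank
# matrix, gene sets, side-effect records, synonym table) with planted
# drug-process perturbations and process/side-effect associations, plus the
# ground truth needed to score recovery.

#' Configuration of a synthetic scenario
#'
#' Defaults mirror the shape of the real data sources at reduced scale: a
#' 2,000-gene universe (for the 22k-probe rank matrix), 200 GO-style sets,
#' 74 drugs bridging the two layers, and 30 planted side effects.
#'
#' @param n_genes size of the gene universe.
#' @param n_sets number of gene sets.
#' @param set_size_range inclusive integer pair of set sizes.
#' @param n_drugs number of drugs.
#' @param n_effects number of side effects; each gets one planted process.
#' @param instances_per_drug treatment instances per drug.
#' @param drugs_per_effect drugs planted per side effect.
#' @param planted_strength fraction in `[0, 1]` of a planted set's genes
#'   forced into the top (up) or bottom (down) decile of the drug's ranked
#'   list; 0 yields a pure-noise scenario.
#' @param seed integer RNG seed; one stream per scenario, forked per
#'   sub-generator so e.g. adding drugs does not reshuffle the gene sets.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_genes = 2000L, n_sets = 200L,
                            set_size_range = c(5L, 30L), n_drugs = 74L,
                            n_effects = 30L, instances_per_drug = 1L,
                            drugs_per_effect = 3L, planted_strength = 0.8,
                            seed = 1L) {
  n_genes <- .assert_count(n_genes, "n_genes", 2L)
  n_sets <- .assert_count(n_sets, "n_sets")
  n_drugs <- .assert_count(n_drugs, "n_drugs")
  n_effects <- .assert_count(n_effects, "n_effects")
  instances_per_drug <- .assert_count(instances_per_drug, "instances_per_drug")
  drugs_per_effect <- .assert_count(drugs_per_effect, "drugs_per_effect")
  .assert_scalar_number(planted_strength, "planted_strength", 0, 1)
  seed <- .assert_count(seed, "seed", lower = 0L)
  if (length(set_size_range) != 2L || any(set_size_range < 1L) ||
      set_size_range[1] > set_size_range[2])
    stop("`set_size_range` must be an increasing pair of positive integers",
         call. = FALSE)
  if (set_size_range[2] >= n_genes)
    stop("maximum set size must be smaller than the gene universe",
         call. = FALSE)
  if (n_effects > n_sets)
    stop("need at least one distinct gene set per planted effect", call. = FALSE)
  if (drugs_per_effect > n_drugs)
    stop("`drugs_per_effect` cannot exceed `n_drugs`", call. = FALSE)
  structure(list(n_genes = n_genes, n_sets = n_sets,
                 set_size_range = as.integer(set_size_range),
                 n_drugs = n_drugs, n_effects = n_effects,
                 instances_per_drug = instances_per_drug,
                 drugs_per_effect = drugs_per_effect,
                 planted_strength = planted_strength, seed = seed),
            class = "scenario_config")
}

# planted frequency scores sit above the 20% filter, decoys below it
.planted_freqs <- c(0.25, 0.5, 0.75)
.decoy_freqs <- c(0.001, 0.01, 0.1)
.freq_description <- function(score) {
  vapply(score, function(s) {
    if (s == 0.001) sample(c("Rare", "Postmarketing"), 1L)
    else if (s == 0.01) "Infrequent"
    else sprintf("%g%%", s * 100)
  }, character(1))
}

#' Generate a complete synthetic scenario
#'
#' Builds the four pipeline inputs plus ground truth.  For every side
#' effect, `drugs_per_effect` drugs are linked to it with an
#' above-threshold frequency and all of them are planted with the same
#' (gene set, direction) perturbation: `planted_strength * Ns` of the set's
#' genes are moved to uniformly random positions inside the top decile of
#' each of those drugs' ranked lists (bottom decile for a down
#' perturbation).  Every drug additionally gets one decoy side-effect
#' record with a below-threshold frequency, and unplanted ranks are
#' uniformly random.  The same seed reproduces the scenario bit for bit.
#'
#' @param config a [scenario_config()].
#' @return A list of class `pse_scenario` with elements `rank_matrix`,
#'   `gene_sets`, `side_effects`, `synonyms`, `ground_truth` (data frames
#'   `drug_process`, `process_effect`, `drug_effect`) and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  sub_seed <- sample.int(.Machine$integer.max - 1L, 6L)

  genes <- sprintf("g%05d", seq_len(config$n_genes))
  drugs <- sprintf("drug%03d", seq_len(config$n_drugs))
  drug_ids <- sprintf("DB%05d", seq_len(config$n_drugs))
  cuis <- sprintf("C%07d", seq_len(config$n_effects))
  effect_names <- sprintf("effect %03d", seq_len(config$n_effects))

  # gene sets
  set.seed(sub_seed[1])
  sizes <- sample(config$set_size_range[1]:config$set_size_range[2],
                  config$n_sets, replace = TRUE)
  go_ids <- sprintf("GO:%07d", seq_len(config$n_sets))
  members <- lapply(sizes, function(k) sample(genes, k))
  sets <- gene_sets(go_ids, sprintf("synthetic process %04d", seq_len(config$n_sets)),
                    members)

  # planted associations: one distinct process per effect, shared by all of
  # the effect's drugs
  set.seed(sub_seed[2])
  planted_sets <- sample(go_ids, config$n_effects)
  planted_dir <- sample(c("up", "down"), config$n_effects, replace = TRUE)
  effect_drugs <- lapply(seq_len(config$n_effects),
                         function(i) sample(drugs, config$drugs_per_effect))
  gt_process_effect <- data.frame(go_id = planted_sets, umls_cui = cuis,
                                  direction = planted_dir,
                                  stringsAsFactors = FALSE)
  gt_drug_process <- do.call(rbind, lapply(seq_len(config$n_effects), function(i)
    data.frame(drug = effect_drugs[[i]], go_id = planted_sets[i],
               direction = planted_dir[i], stringsAsFactors = FALSE)))
  gt_drug_process <- unique(gt_drug_process)

  # side-effect layer: planted links above the frequency filter
  set.seed(sub_seed[3])
  gt_drug_effect <- do.call(rbind, lapply(seq_len(config$n_effects), function(i)
    data.frame(drug = effect_drugs[[i]], umls_cui = cuis[i],
               freq_score = sample(.planted_freqs, config$drugs_per_effect,
                                   replace = TRUE),
               stringsAsFactors = FALSE)))

  # decoy records: one per drug, below the filter
  set.seed(sub_seed[4])
  decoys <- data.frame(drug = drugs,
                       umls_cui = sample(cuis, config$n_drugs, replace = TRUE),
                       freq_score = sample(.decoy_freqs, config$n_drugs,
                                           replace = TRUE),
                       stringsAsFactors = FALSE)
  planted_key <- paste(gt_drug_effect$drug, gt_drug_effect$umls_cui)
  decoys <- decoys[!(paste(decoys$drug, decoys$umls_cui) %in% planted_key), ,
                   drop = FALSE]
  se_all <- rbind(gt_drug_effect, decoys)
  side_effects <- side_effect_records(
    compound_id = se_all$drug,
    umls_cui = se_all$umls_cui,
    effect_name = effect_names[match(se_all$umls_cui, cuis)],
    freq_description = .freq_description(se_all$freq_score),
    freq_score = se_all$freq_score)

  # synonym table: primary name + one synonym + one capitalized brand name
  synonyms <- synonym_table(
    canonical_id = rep(drug_ids, each = 3L),
    name = as.vector(rbind(drugs, paste0(drugs, "_syn"),
                           paste0("Brand", sub("drug", "", drugs)))),
    name_type = rep(c("primary", "synonym", "brand"), config$n_drugs))

  # rank matrix with planted decile placements
  set.seed(sub_seed[5])
  n <- config$n_genes
  decile <- max(1L, floor(0.10 * n))
  plants_by_drug <- split(gt_drug_process, gt_drug_process$drug)
  inst_per <- config$instances_per_drug
  inst_ids <- as.vector(vapply(drugs, function(d)
    sprintf("%s_i%02d", d, seq_len(inst_per)), character(inst_per)))
  inst_drug <- rep(drugs, each = inst_per)
  ranks <- matrix(0L, n, length(inst_ids), dimnames = list(genes, inst_ids))
  for (j in seq_along(inst_ids)) {
    plant <- plants_by_drug[[inst_drug[j]]]
    placed_gene <- character(0)
    placed_dir <- character(0)
    if (!is.null(plant) && config$planted_strength > 0) {
      for (r in seq_len(nrow(plant))) {
        sg <- sets[[plant$go_id[r]]]$genes
        m <- round(config$planted_strength * length(sg))
        if (m < 1L) next
        pick <- sample(sg, m)
        new <- !(pick %in% placed_gene)
        placed_gene <- c(placed_gene, pick[new])
        placed_dir <- c(placed_dir, rep(plant$direction[r], sum(new)))
      }
    }
    pos <- rep(NA_character_, n)
    for (d in c("up", "down")) {
      pg <- placed_gene[placed_dir == d]
      if (!length(pg)) next
      slots <- if (d == "up") seq_len(decile) else (n - decile + 1L):n
      if (length(pg) > length(slots))
        stop(sprintf(
          "instance '%s': %d planted genes exceed the %s decile (%d slots)",
          inst_ids[j], length(pg), if (d == "up") "top" else "bottom",
          length(slots)), call. = FALSE)
      pos[slots[sample.int(length(slots), length(pg))]] <- pg
    }
    free <- which(is.na(pos))
    pos[free] <- sample(setdiff(genes, placed_gene))
    ranks[match(pos, genes), j] <- seq_len(n)
  }
  rm <- rank_matrix(ranks, data.frame(instance_id = inst_ids,
                                      drug = inst_drug,
                                      stringsAsFactors = FALSE))

  structure(list(rank_matrix = rm, gene_sets = sets,
                 side_effects = side_effects, synonyms = synonyms,
                 ground_truth = list(drug_process = gt_drug_process,
                                     process_effect = gt_process_effect,
                                     drug_effect = gt_drug_effect),
                 config = config),
            class = "pse_scenario")
}

#' @export
print.pse_scenario <- function(x, ...) {
  cat(sprintf(paste0("<pse_scenario> %d genes, %d sets, %d drugs (%d instances), ",
                     "%d effects\n  planted: %d drug-process perturbations, ",
                     "%d process-effect links, strength %.2f, seed %d\n"),
              x$config$n_genes, x$config$n_sets, x$config$n_drugs,
              ncol(x$rank_matrix$ranks), x$config$n_effects,
              nrow(x$ground_truth$drug_process),
              nrow(x$ground_truth$process_effect),
              x$config$planted_strength, x$config$seed))
  invisible(x)
}

#' Rename side-effect-layer drugs to brand aliases
#'
#' Stress-tests the synonym-normalization step: rewrites the drug name of
#' the chosen fraction of drugs (first `round(fraction * n_drugs)` drugs in
#' sorted order, deterministically) everywhere in the scenario's
#' side-effect records to the brand-name alias of the same canonical drug.
#' The synonym table already contains the alias, so a correct merge
#' recovers the same bridge.
#'
#' @param scenario a [generate_scenario()] result.
#' @param fraction fraction of drugs to alias, in `[0, 1]`.
#' @return The modified scenario.
#' @export
make_synonym_collisions <- function(scenario, fraction) {
  stopifnot(inherits(scenario, "pse_scenario"))
  .assert_scalar_number(fraction, "fraction", 0, 1)
  drugs <- sort(unique(scenario$rank_matrix$instances$drug))
  k <- round(fraction * length(drugs))
  if (k == 0L) return(scenario)
  target <- drugs[seq_len(k)]
  syn <- scenario$synonyms
  for (d in target) {
    cid <- syn$canonical_id[syn$name_type == "primary" & syn$name == d]
    brand <- syn$name[syn$canonical_id == cid & syn$name_type == "brand"][1L]
    scenario$side_effects$compound_id[
      scenario$side_effects$compound_id == d] <- brand
  }
  scenario
}
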