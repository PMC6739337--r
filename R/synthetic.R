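# Synthetic cohort generator. Emulates exactly the statistical structure
# the analysis exploits -- compounds clustered into latent groups with
# well-separated signature centroids ("similar signature implies similar
# behaviour" holds by construction), psychoactive flags concentrated in a
# subset of groups, and indications whose approved (always
# non-psychoactive) drugs are preferentially drawn from those
# psychoactive-bearing groups -- without imitating the marginal
# distribution of real docking scores.
#
# Flagging discipline: groups are designated psychoactive-bearing in
# random order; within a designated group at most half the members (and
# never all of them) are flagged, so every bearing group keeps
# non-psychoactive members able to serve as approved drugs -- the donors
# whose signature neighbourhoods carry the planted psychoactive
# enrichment. A psychoactive_fraction so high that it cannot be met this
# way (e.g. 1) is an infeasibility error.
#
# Enrichment discipline: each approved drug of a mental-health indication
# is drawn from the bearing-group donor pool with probability `enrichment`
# and from the non-bearing pool otherwise, so the probability of a
# bearing-group donor is exactly `enrichment`. Setting `enrichment` to the
# cohort's base rate (the bearing share of all donors; `enrichment =
# "base"`) makes mental-health indications statistically indistinguishable
# from the rest -- the calibration null.

#' Specification of a synthetic cohort
#'
#' Defaults are the package's scaled-down rendering of the study
#' conditions: a library in which roughly 12% of compounds are
#' psychoactive (mirroring 428 of 3,733) and a minority of indications are
#' mental-health, with a strong but imperfect planted preference
#' (enrichment 0.8) of mental-health indications for psychoactive-bearing
#' signature groups.
#'
#' @param n_compounds,n_proteins library dimensions.
#' @param n_groups latent compound clusters (each compound belongs to
#'   exactly one).
#' @param noise_sd within-group signature noise (score units).
#' @param centroid_separation scale of the between-group centroid spacing;
#'   default `12.5 * noise_sd` (floor 1), which guarantees a minimal
#'   between-centroid RMSD of at least 10 x `noise_sd`.
#' @param psychoactive_fraction target fraction of compounds flagged
#'   psychoactive.
#' @param n_indications,mental_health_fraction indication panel size and
#'   mental-health share.
#' @param drugs_per_indication approved drugs per indication (>= 2).
#' @param mh_drugs_per_indication optional override of the approved-drug
#'   count for mental-health indications (default `NULL` = same as
#'   `drugs_per_indication`); setting it higher reproduces the drug-rich
#'   mental-health pharmacopoeia of real drug-indication maps.
#' @param enrichment probability in [0, 1] that an approved drug of a
#'   mental-health indication is drawn from a psychoactive-bearing group;
#'   `"base"` uses the cohort's own bearing-donor base rate (calibration
#'   null).
#' @param seed integer seed; same spec, same seed, bit-identical cohort.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 200L, n_proteins = 64L, n_groups = 20L,
                           noise_sd = 0.1, centroid_separation = NULL,
                           psychoactive_fraction = 0.12,
                           n_indications = 40L, mental_health_fraction = 0.25,
                           drugs_per_indication = 5L,
                           mh_drugs_per_indication = NULL,
                           enrichment = 0.8, seed = 1L) {
  if (n_groups > n_compounds) stop("n_groups must not exceed n_compounds", call. = FALSE)
  if (drugs_per_indication < 2) stop("drugs_per_indication must be >= 2", call. = FALSE)
  if (drugs_per_indication > n_compounds) {
    stop("drugs_per_indication must not exceed n_compounds", call. = FALSE)
  }
  if (psychoactive_fraction < 0 || psychoactive_fraction > 1) {
    stop("psychoactive_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!identical(enrichment, "base") &&
      (!is.numeric(enrichment) || enrichment < 0 || enrichment > 1)) {
    stop("enrichment must lie in [0, 1] or be \"base\"", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_proteins = as.integer(n_proteins),
         n_groups = as.integer(n_groups),
         noise_sd = noise_sd,
         centroid_separation = centroid_separation %||% max(12.5 * noise_sd, 1),
         psychoactive_fraction = psychoactive_fraction,
         n_indications = as.integer(n_indications),
         mental_health_fraction = mental_health_fraction,
         drugs_per_indication = as.integer(drugs_per_indication),
         mh_drugs_per_indication =
           if (is.null(mh_drugs_per_indication)) NULL
           else as.integer(mh_drugs_per_indication),
         enrichment = enrichment,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Deterministic core: everything below runs inside one seeded RNG stream.
generate_cohort_impl <- function(spec) {
  n <- spec$n_compounds; p <- spec$n_proteins; G <- spec$n_groups
  cmp_ids <- sprintf("syn-c%04d", seq_len(n))
  prot_ids <- sprintf("syn-p%04d", seq_len(p))
  ind_ids <- sprintf("syn-d%03d", seq_len(spec$n_indications))

  group_of <- sample(rep_len(seq_len(G), n))
  base <- stats::runif(p, 0.8, 1.2)
  centroids <- outer(seq_len(G) * spec$centroid_separation, base)
  scores <- centroids[group_of, , drop = FALSE] +
    matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
  dimnames(scores) <- list(cmp_ids, prot_ids)

  # psychoactive flags: designate groups in random order, flagging at most
  # half of each designated group (never all members) so bearing groups
  # retain non-psychoactive donors
  target <- round(spec$psychoactive_fraction * n)
  psy <- logical(n)
  bearing <- integer(0)
  for (g in sample(seq_len(G))) {
    if (target <= 0) break
    members <- which(group_of == g)
    k <- min(max(1L, length(members) %/% 2L), length(members) - 1L, target)
    if (k <= 0) next
    psy[sample(members, k)] <- TRUE
    bearing <- c(bearing, g)
    target <- target - k
  }
  if (target > 0) {
    stop("infeasible spec: psychoactive_fraction too high to keep ",
         "non-psychoactive donors in every psychoactive-bearing group", call. = FALSE)
  }
  class_cycle <- c("phenethylamine", "tryptamine", "amphetamine",
                   "cathinone", "cannabinoid", "other")
  chem_class <- rep("none", n)
  for (i in seq_along(bearing)) {
    g <- bearing[i]
    chem_class[group_of == g & psy] <- class_cycle[(i - 1L) %% 6L + 1L]
  }

  donors <- which(!psy)
  bearing_donors <- donors[group_of[donors] %in% bearing]
  other_donors <- setdiff(donors, bearing_donors)
  b_rate <- if (length(donors)) length(bearing_donors) / length(donors) else 0
  enr <- if (identical(spec$enrichment, "base")) b_rate else spec$enrichment

  n_mh <- round(spec$mental_health_fraction * spec$n_indications)
  is_mh <- logical(spec$n_indications)
  is_mh[sample(spec$n_indications, n_mh)] <- TRUE

  approved <- vector("list", spec$n_indications)
  for (i in seq_len(spec$n_indications)) {
    k <- if (is_mh[i] && !is.null(spec$mh_drugs_per_indication)) {
      spec$mh_drugs_per_indication
    } else spec$drugs_per_indication
    if (is_mh[i] && enr > 0) {
      kb <- stats::rbinom(1, k, enr)
      if (kb > length(bearing_donors) || (k - kb) > length(other_donors)) {
        stop("infeasible spec: donor pools too small for drugs_per_indication",
             call. = FALSE)
      }
      picks <- c(if (kb > 0) sample(bearing_donors, kb),
                 if (k - kb > 0) sample(other_donors, k - kb))
    } else {
      if (k > length(if (is_mh[i]) other_donors else donors)) {
        stop("infeasible spec: donor pool too small for drugs_per_indication",
             call. = FALSE)
      }
      picks <- sample(if (is_mh[i]) other_donors else donors, k)
    }
    approved[[i]] <- cmp_ids[sort(picks)]
  }

  compounds <- compound_table(cmp_ids, name = cmp_ids, smiles = NA_character_,
                              is_psychoactive = psy, chem_class = chem_class)
  indications <- indication_table(ind_ids, name = ind_ids,
                                  is_mental_health = is_mh,
                                  approved = approved,
                                  compounds = compounds)
  truth <- list(
    group_of = stats::setNames(group_of, norm_id(cmp_ids)),
    bearing_groups = sort(bearing),
    base_rate = b_rate,
    enrichment_used = enr,
    approved_groups = stats::setNames(
      lapply(approved, function(a) sort(unique(group_of[match(a, cmp_ids)]))),
      norm_id(ind_ids))
  )
  list(matrix = interaction_matrix(scores),
       compounds = compounds,
       indications = indications,
       truth = truth,
       spec = spec)
}

#' Generate a synthetic cohort
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_cohort` with elements `matrix`
#'   ([interaction_matrix()]), `compounds` ([compound_table()]),
#'   `indications` ([indication_table()]), `truth` (see [planted_truth()])
#'   and `spec`. Identical specs (including seed) give bit-identical
#'   cohorts.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- with_rng(spec$seed, generate_cohort_impl(spec))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d compounds x %d proteins, %d groups ",
                     "(%d psychoactive-bearing), %d indications (%d mental-health)\n"),
              nrow(x$matrix), ncol(x$matrix), x$spec$n_groups,
              length(x$truth$bearing_groups), nrow(x$indications),
              sum(x$indications$is_mental_health)))
  invisible(x)
}

#' Planted ground truth of a synthetic cohort
#'
#' Re-derives (deterministically, from the spec alone) the latent group of
#' every compound and, per indication, the groups its approved drugs came
#' from -- the reference for parameter-recovery tests.
#'
#' @param spec the [synthetic_spec()] used in a prior [generate_cohort()]
#'   call.
#' @return list with `group_of` (named integer vector), `bearing_groups`,
#'   `base_rate` (bearing share of the donor pool), `enrichment_used`, and
#'   `approved_groups` (per indication, sorted unique donor groups).
#' @export
planted_truth <- function(spec) {
  generate_cohort(spec)$truth
}

#' Write a synthetic cohort to TSV files
#'
#' Emits `matrix.tsv`, `compounds.tsv`, `indications.tsv` (the three
#' canonical input tables) plus `truth.tsv` (compound, latent group,
#' psychoactive flag) into a directory.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_matrix(cohort$matrix, file.path(dir, "matrix.tsv"), "tsv")
  utils::write.table(as.data.frame(cohort$compounds), file.path(dir, "compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ind <- as.data.frame(cohort$indications)
  ind$approved_compound_ids <- vapply(ind$approved, paste, "", collapse = ";")
  ind$approved <- NULL
  ind$usable <- NULL
  utils::write.table(ind, file.path(dir, "indications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(compound_id = names(cohort$truth$group_of),
                      group = unname(cohort$truth$group_of),
                      is_psychoactive = cohort$compounds$is_psychoactive[
                        match(names(cohort$truth$group_of),
                              cohort$compounds$compound_id)])
  utils::write.table(truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
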