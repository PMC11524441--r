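# Seeded generators producing compendium, coupled DE tables, curated
# annotations and target sets with the statistical structure the analysis
# layer assumes, so every stage is testable without external downloads.
#
# One integer seed governs all generators; each generator derives its own
# sub-stream through a fixed offset, so adding a generator call never
# perturbs the outputs of another.

.oasig_cache <- new.env(parent = emptyenv())

seed_offset <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483647L
}

# Run `expr` under a private, fixed RNG stream and restore the caller's RNG
# state afterwards. Used for calibration, which must be a pure function of
# the model parameters, not of the user's seed.
with_private_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators.
#' Defaults describe the emulated study conditions: a compendium of 800
#' fold-change profiles over 15,000 genes with 5 related datasets sharing
#' 60% of a planted injury signature; two coupled DE tables with a target
#' Spearman correlation of 0.8 among shared significant genes and 1%
#' sign-discordance; a curated annotation with 217 Protective and 199
#' Detrimental genes planted at odds ratio 3 among upregulated genes; and a
#' 120-gene predicted target set strongly planted (odds ratio 20) among
#' upregulated genes.
#'
#' @param seed integer master seed; identical configuration and seed give
#'   byte-identical outputs.
#' @param n_genes,n_datasets,n_related compendium dimensions
#'   (`n_related < n_datasets`).
#' @param mixing signature-sharing coefficient in `[0, 1]`: related datasets
#'   and the query are `mixing * signature + noise`.
#' @param noise_sd standard deviation of per-gene log2FC noise; also the
#'   standard error of the observed log2FC in the DE-table sampling model.
#' @param frac_de fraction of genes with a true shared effect.
#' @param effect_log2fc_sd spread (half-normal scale) of true log2FC effect
#'   magnitudes above `effect_min_log2fc`.
#' @param effect_min_log2fc minimum magnitude of a true effect (default
#'   `log2(1.5)`, the study's fold-change threshold): truly regulated genes
#'   are modelled as having at least a biologically meaningful effect, which
#'   is what allows high rank correlation with low sign-discordance among
#'   significant genes.
#' @param target_rho target Spearman correlation among genes significant in
#'   both coupled DE tables.
#' @param discordance probability that a true-effect gene is sign-flipped in
#'   table B (fraction regulated in opposing directions).
#' @param n_protective,n_detrimental,n_ambiguous curated annotation sizes.
#' @param annotation_odds_ratio planted Protective-vs-Detrimental odds ratio
#'   among upregulated genes.
#' @param target_set_size,target_odds_ratio predicted-target set size and its
#'   planted enrichment among upregulated genes.
#' @param dropout_max per-dataset gene dropout rates are uniform on
#'   `[0, dropout_max]`, so pairwise gene intersections vary.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_genes = 15000L, n_datasets = 800L,
                       n_related = 5L, mixing = 0.6, noise_sd = 0.3,
                       frac_de = 0.15, effect_log2fc_sd = 1.5,
                       effect_min_log2fc = log2(1.5),
                       target_rho = 0.8, discordance = 0.01,
                       n_protective = 217L, n_detrimental = 199L,
                       n_ambiguous = 60L, annotation_odds_ratio = 3,
                       target_set_size = 120L, target_odds_ratio = 20,
                       dropout_max = 0.3) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_datasets = as.integer(n_datasets),
              n_related = as.integer(n_related), mixing = mixing,
              noise_sd = noise_sd, frac_de = frac_de,
              effect_log2fc_sd = effect_log2fc_sd,
              effect_min_log2fc = effect_min_log2fc, target_rho = target_rho,
              discordance = discordance,
              n_protective = as.integer(n_protective),
              n_detrimental = as.integer(n_detrimental),
              n_ambiguous = as.integer(n_ambiguous),
              annotation_odds_ratio = annotation_odds_ratio,
              target_set_size = as.integer(target_set_size),
              target_odds_ratio = target_odds_ratio,
              dropout_max = dropout_max)
  chk <- function(cond, msg) if (!cond) stop_oasig(msg, "oasig_config_error")
  chk(is.finite(cfg$seed), "seed must be a finite integer")
  chk(cfg$n_genes >= 1, "n_genes must be positive")
  chk(cfg$n_datasets >= 1, "n_datasets must be positive")
  chk(cfg$n_related >= 0 && cfg$n_related < cfg$n_datasets,
      "need 0 <= n_related < n_datasets")
  chk(cfg$mixing >= 0 && cfg$mixing <= 1, "mixing must lie in [0, 1]")
  chk(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  chk(cfg$frac_de >= 0 && cfg$frac_de <= 1, "frac_de must lie in [0, 1]")
  chk(cfg$effect_log2fc_sd > 0, "effect_log2fc_sd must be positive")
  chk(cfg$effect_min_log2fc >= 0, "effect_min_log2fc must be non-negative")
  chk(cfg$target_rho >= -1 && cfg$target_rho <= 1,
      "target_rho must lie in [-1, 1]")
  chk(cfg$discordance >= 0 && cfg$discordance <= 1,
      "discordance must lie in [0, 1]")
  chk(cfg$n_protective > 0 && cfg$n_detrimental > 0 && cfg$n_ambiguous >= 0,
      "annotation sizes must be positive")
  chk(cfg$annotation_odds_ratio > 0, "annotation_odds_ratio must be positive")
  chk(cfg$target_set_size > 0 && cfg$target_odds_ratio > 0,
      "target set size and odds ratio must be positive")
  chk(cfg$dropout_max >= 0 && cfg$dropout_max < 1,
      "dropout_max must lie in [0, 1)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-data configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Generate a synthetic fold-change compendium with a planted signature
#'
#' Draws a latent per-gene signature `s ~ Normal(0, 1)`. Related datasets
#' and the query are `mixing * s` plus independent Normal(0, `noise_sd`)
#' noise; unrelated datasets are pure noise. Each dataset loses a random
#' fraction of genes (uniform on `[0, dropout_max]`) so pairwise
#' intersections vary; the query keeps all genes.
#'
#' @param cfg a [sim_config()].
#' @return List with `compendium` (a [compendium()]), `query`
#'   (a [fold_change_profile()]) and `related_ids` (character vector of the
#'   planted datasets).
#' @export
generate_compendium <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed_offset(cfg$seed, 101L))
  n <- cfg$n_genes
  genes <- gene_names(n)
  s <- stats::rnorm(n)
  ids <- sprintf("DS%04d", seq_len(cfg$n_datasets))
  related <- sort(sample.int(cfg$n_datasets, cfg$n_related))
  profiles <- vector("list", cfg$n_datasets)
  for (j in seq_len(cfg$n_datasets)) {
    base <- if (j %in% related) cfg$mixing * s else 0
    vals <- base + stats::rnorm(n, 0, cfg$noise_sd)
    names(vals) <- genes
    drop_rate <- stats::runif(1, 0, cfg$dropout_max)
    keep <- stats::runif(n) >= drop_rate
    if (!any(keep)) keep[1] <- TRUE
    profiles[[j]] <- fold_change_profile(
      ids[j], vals[keep], species = "Mus musculus",
      description = if (j %in% related) "planted injury signature"
                    else "background")
  }
  meta <- data.frame(dataset_id = ids, species = "Mus musculus",
                     label = ifelse(seq_len(cfg$n_datasets) %in% related,
                                    "planted injury signature", "background"),
                     stringsAsFactors = FALSE)
  query_vals <- cfg$mixing * s + stats::rnorm(n, 0, cfg$noise_sd)
  names(query_vals) <- genes
  list(compendium = compendium(profiles, meta),
       query = fold_change_profile("QUERY", query_vals,
                                   species = "Mus musculus",
                                   description = "synthetic query"),
       related_ids = ids[related])
}

# Calibrate the magnitude-noise scale of the coupled-table model on a
# common-random-numbers Monte-Carlo replica of the full pipeline (fixed
# private seed, memoised). True-effect genes share a signed effect mu; the
# two tables observe mu with independent log-normal *magnitude* noise
# (sign-preserving, so rank scrambling and sign flips are decoupled) and a
# fraction `discordance` of true-effect genes is sign-flipped in table B
# (flips do not change |log2FC|, so the expected sign-discordance among
# jointly significant genes equals the flip rate exactly). The magnitude
# noise `w` is root-found so that the expected Spearman correlation among
# genes significant (BH FDR < fdr_threshold) in BOTH tables equals
# target_rho; joint-significance selection truncates towards large |log2FC|,
# so no closed form applies. Because the sign split keeps ranks partially
# aligned however strong the magnitude noise, low target_rho is only
# feasible together with a matching discordance; infeasible pairs error.
calibrate_coupling <- function(tau, mmin, se, frac_de, target_rho, discordance,
                               fdr_threshold = 0.05, n_cal = 40000L) {
  if (target_rho <= 0)
    stop_oasig("infeasible target_rho: shared-effect tables cannot have non-positive expected correlation",
               "oasig_config_error")
  key <- paste(tau, mmin, se, frac_de, target_rho, discordance, fdr_threshold,
               n_cal, sep = "|")
  if (!is.null(.oasig_cache[[key]])) return(.oasig_cache[[key]])
  n_de <- max(1L, round(frac_de * n_cal))
  draws <- with_private_rng(780069L, list(
    z_mu = stats::rnorm(n_de), s_mu = sign(stats::runif(n_de) - 0.5),
    za = stats::rnorm(n_cal), zb = stats::rnorm(n_cal),
    u_flip = stats::runif(n_de)))
  de <- seq_len(n_de)
  mu <- numeric(n_cal)
  mu[de] <- draws$s_mu * (mmin + abs(tau * draws$z_mu))
  flip <- de[draws$u_flip < discordance]
  replica <- function(w) {
    xa <- se * draws$za
    xb <- se * draws$zb
    xa[de] <- mu[de] * exp(w * draws$za[de])
    xb[de] <- mu[de] * exp(w * draws$zb[de])
    xb[flip] <- -xb[flip]
    fa <- stats::p.adjust(2 * stats::pnorm(-abs(xa) / se), method = "BH")
    fb <- stats::p.adjust(2 * stats::pnorm(-abs(xb) / se), method = "BH")
    sel <- fa < fdr_threshold & fb < fdr_threshold
    if (sum(sel) < 50)
      stop_oasig("infeasible configuration: too few jointly significant genes to calibrate",
                 "oasig_config_error")
    stats::cor(xa[sel], xb[sel], method = "spearman")
  }
  objective <- function(w) replica(w) - target_rho
  f0 <- objective(0)
  w <- if (f0 <= 0) {
    # noise-free magnitudes cannot exceed the target (or exactly meet it,
    # e.g. target_rho = 1 with discordance = 0)
    if (f0 < -0.02)
      stop_oasig(sprintf(
        "infeasible (target_rho, discordance): maximum achievable Spearman at %.0f%% discordance is %.3f",
        100 * discordance, f0 + target_rho), "oasig_config_error")
    0
  } else {
    upper <- 6
    fu <- objective(upper)
    if (fu > 0)
      stop_oasig(sprintf(
        "infeasible (target_rho, discordance): minimum achievable Spearman at %.0f%% discordance is %.3f; request more discordance for lower correlations",
        100 * discordance, fu + target_rho), "oasig_config_error")
    stats::uniroot(objective, c(0, upper), tol = 1e-4)$root
  }
  .oasig_cache[[key]] <- w
  w
}

#' Generate two coupled differential-expression tables
#'
#' A fraction `frac_de` of genes receives a shared true effect with random
#' sign and magnitude `effect_min_log2fc + |Normal(0, effect_log2fc_sd)|`.
#' Each table observes the effect with independent sign-preserving
#' log-normal magnitude noise (the two emulated injury models regulate the
#' same genes in the same direction with different strengths), whose scale
#' is calibrated (see Details) so that the expected Spearman correlation
#' among genes significant in both tables matches `target_rho`; a fraction
#' `discordance` of true-effect genes is sign-flipped in table B, which
#' fixes the expected sign-discordance exactly. Null genes observe pure
#' Normal(0, `noise_sd`) noise. P-values come from the stated testing model
#' (`log2FC ~ Normal(mu, noise_sd^2)`, two-sided z-test) and FDR from
#' Benjamini-Hochberg across each table.
#'
#' @details Joint-significance selection truncates towards large effects and
#'   inflates the rank correlation above its unconditional value, so the
#'   coupling noise is set by root-finding on a deterministic
#'   common-random-numbers Monte-Carlo replica of the pipeline (fixed
#'   internal seed, independent of `cfg$seed`, memoised per parameter set).
#'   Infeasible `(target_rho, discordance)` combinations raise a
#'   configuration error.
#'
#' @param cfg a [sim_config()].
#' @return List with `table_a`, `table_b` ([de_table()]s) and `truth`
#'   (list: `de_genes`, `flipped`, `mu`, `magnitude_noise`).
#' @export
generate_linked_de_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$noise_sd <= 0)
    stop_oasig("noise_sd must be positive for DE-table generation",
               "oasig_config_error")
  n <- cfg$n_genes
  n_de <- round(cfg$frac_de * n)
  w <- if (n_de > 0)
    calibrate_coupling(cfg$effect_log2fc_sd, cfg$effect_min_log2fc,
                       cfg$noise_sd, cfg$frac_de, cfg$target_rho,
                       cfg$discordance)
  else NA_real_
  set.seed(seed_offset(cfg$seed, 202L))
  genes <- gene_names(n)
  de_idx <- sort(sample.int(n, n_de))
  de <- logical(n); de[de_idx] <- TRUE
  mu <- numeric(n)
  mu[de_idx] <- sign(stats::runif(n_de) - 0.5) *
    (cfg$effect_min_log2fc + abs(stats::rnorm(n_de, 0, cfg$effect_log2fc_sd)))
  ea <- stats::rnorm(n); eb <- stats::rnorm(n)
  xa <- ifelse(de, mu * exp(w * ea), cfg$noise_sd * ea)
  xb <- ifelse(de, mu * exp(w * eb), cfg$noise_sd * eb)
  flip <- logical(n)
  if (n_de > 0) flip[de_idx] <- stats::runif(n_de) < cfg$discordance
  xb[flip] <- -xb[flip]
  pa <- pmax(2 * stats::pnorm(-abs(xa) / cfg$noise_sd), 1e-300)
  pb <- pmax(2 * stats::pnorm(-abs(xb) / cfg$noise_sd), 1e-300)
  ta <- de_table(genes, xa, pa, stats::p.adjust(pa, method = "BH"),
                 dataset_id = "MODEL_A", species = "Mus musculus")
  tb <- de_table(genes, xb, pb, stats::p.adjust(pb, method = "BH"),
                 dataset_id = "MODEL_B", species = "Mus musculus")
  list(table_a = ta, table_b = tb,
       truth = list(de_genes = genes[de_idx], flipped = genes[flip],
                    mu = stats::setNames(mu[de_idx], genes[de_idx]),
                    magnitude_noise = w))
}

# Draw the in-group count of a without-replacement sample of size `n` from a
# population of `N` (of which `K` are in the group) under Fisher's
# noncentral hypergeometric distribution with odds ratio `or`.
rfisher_nchyper <- function(N, K, n, or) {
  lo <- max(0L, n - (N - K)); hi <- min(n, K)
  a <- lo:hi
  logw <- lchoose(K, a) + lchoose(N - K, n - a) + a * log(or)
  w <- exp(logw - max(logw))
  if (length(a) == 1L) a else sample(a, 1L, prob = w)
}

#' Generate a curated annotation and target set with planted enrichment
#'
#' Builds an OATargets-style annotation and a predicted-target gene set over
#' a background, planting enrichment among the upregulated genes:
#' Detrimental genes are drawn uniformly from the background, Protective
#' genes from the remainder with a Fisher noncentral hypergeometric tilt of
#' `annotation_odds_ratio` towards `up` (so the Protective-vs-Detrimental
#' odds ratio among DE genes equals the configured value in expectation),
#' and Ambiguous genes uniformly from what is left. The target set is drawn
#' the same way at `target_odds_ratio`.
#'
#' @param cfg a [sim_config()].
#' @param up,down character vectors of up-/downregulated genes.
#' @param background character vector of detected genes
#'   (`up`, `down` subsets of it).
#' @return List with `annotation` (a [curated_annotation()]), `targets`
#'   (a [target_gene_set()]) and `truth` (the planted odds ratios).
#' @export
generate_annotation_and_targets <- function(cfg, up, down, background) {
  stopifnot(inherits(cfg, "sim_config"))
  bg <- unique(norm_symbols(background))
  up <- intersect(unique(norm_symbols(up)), bg)
  if (cfg$n_protective + cfg$n_detrimental + cfg$n_ambiguous > length(bg))
    stop_oasig("requested annotation sizes exceed the background",
               "oasig_config_error")
  if (cfg$target_set_size > length(bg))
    stop_oasig("requested target set size exceeds the background",
               "oasig_config_error")
  set.seed(seed_offset(cfg$seed, 303L))
  det <- sample(bg, cfg$n_detrimental)
  rem <- setdiff(bg, det)
  up_rem <- intersect(rem, up)
  a <- rfisher_nchyper(length(rem), length(up_rem), cfg$n_protective,
                       cfg$annotation_odds_ratio)
  prot <- c(sample(up_rem, a), sample(setdiff(rem, up_rem),
                                      cfg$n_protective - a))
  rem2 <- setdiff(rem, prot)
  amb <- if (cfg$n_ambiguous > 0) sample(rem2, cfg$n_ambiguous) else character()
  ann <- curated_annotation(
    c(prot, det, amb),
    c(rep("Protective", length(prot)), rep("Detrimental", length(det)),
      rep("Ambiguous", length(amb))))
  at <- rfisher_nchyper(length(bg), length(up), cfg$target_set_size,
                        cfg$target_odds_ratio)
  tg <- c(sample(up, at), sample(setdiff(bg, up), cfg$target_set_size - at))
  targets <- target_gene_set("miR-sim", tg,
                             description = "synthetic predicted target set")
  list(annotation = ann, targets = targets,
       truth = list(annotation_odds_ratio = cfg$annotation_odds_ratio,
                    target_odds_ratio = cfg$target_odds_ratio))
}
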