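#' Effect configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the generative model for study cohorts:
#' community composition, the zero-inflated negative binomial observation
#' model, race-by-BV interaction strengths, and the linear models linking
#' taxon abundances to the four Amsel clinical signs.
#'
#' Defaults emulate the structure reported for vaginal microbiota studies:
#' non-BV communities dominated by one Lactobacillus species holding ~90%
#' of reads; diverse BV communities with log-normal abundances organised
#' into co-occurring sub-groups via shared latent factors; sequencing depth
#' log-normal around 1620 reads per participant with coefficient of
#' variation 0.5.
#'
#' @param dominance_conc Beta concentration for the dominant-taxon share in
#'   non-BV samples; the share is `0.5 + 0.5 * Beta(0.8 * c, 0.2 * c)`, so it
#'   always exceeds 50% and averages ~90%.
#' @param bv_meanlog,bv_sdlog log-normal parameters of BV-community taxon
#'   abundances (before normalisation).
#' @param subgroups list of character vectors of species taxids; members of
#'   one sub-group share a latent factor and therefore co-occur.
#' @param subgroup_loading loading of each sub-group member on its latent
#'   factor (log scale).
#' @param interaction named numeric vector: per-taxon race-by-BV interaction
#'   strength on the log count scale (applied for the first race level).
#' @param sign_coefs named list with one numeric vector per clinical sign
#'   (`ph`, `whiff`, `clue`, `discharge`), each named by taxid: coefficients
#'   of the linear sign model on log(count + 0.5).
#' @param pi zero-inflation probability of the count observation model.
#' @param theta negative binomial dispersion (size) parameter.
#' @param depth_mean,depth_cv mean and coefficient of variation of the
#'   log-normal per-sample sequencing depth.
#' @param depth_model `"zinb"` draws each taxon count from the ZINB
#'   observation model (realised depth varies around the requested depth);
#'   `"multinomial"` draws reads by multinomial sampling so row sums equal
#'   the requested depths exactly.
#' @return a list of class `effect_config`.
#' @export
effect_config <- function(dominance_conc = 10,
                          bv_meanlog = 0, bv_sdlog = 1.2,
                          subgroups = NULL,
                          subgroup_loading = 1.0,
                          interaction = NULL,
                          sign_coefs = NULL,
                          pi = 0.15, theta = 1.5,
                          depth_mean = 1620, depth_cv = 0.5,
                          depth_model = c("zinb", "multinomial")) {
  stopifnot(pi >= 0, pi < 1, theta > 0, dominance_conc > 0,
            depth_mean > 0, depth_cv > 0)
  depth_model <- match.arg(depth_model)
  structure(
    list(
      dominance_conc = dominance_conc,
      bv_meanlog = bv_meanlog, bv_sdlog = bv_sdlog,
      subgroups = subgroups, subgroup_loading = subgroup_loading,
      interaction = interaction,
      sign_coefs = sign_coefs,
      pi = pi, theta = theta,
      depth_mean = depth_mean, depth_cv = depth_cv,
      depth_model = depth_model
    ),
    class = "effect_config"
  )
}

default_subgroups <- function(taxa) {
  g1 <- intersect(c("Gardnerella_vaginalis_like", "Atopobium_vaginae_like",
                    "Eggerthella_like", "Megasphaera_type1_like",
                    "Sneathia_sanguinegens_like", "Leptotrichia_amnionii_like"), taxa)
  g2 <- intersect(c("BVAB1", "BVAB2", "Prevotella_amnii_like"), taxa)
  Filter(function(g) length(g) >= 2, list(anaerobe_core = g1, bvab_group = g2))
}

default_sign_coefs <- function(taxa) {
  bv_like <- setdiff(taxa, c("Lactobacillus_crispatus_like", "Lactobacillus_iners_like"))
  mk <- function(pos, pos_w, neg, neg_w) {
    stats::setNames(
      c(rep(pos_w, length(pos)), rep(neg_w, length(neg))),
      c(pos, neg)
    )
  }
  crisp <- intersect("Lactobacillus_crispatus_like", taxa)
  list(
    ph = mk(bv_like, 0.08, crisp, -0.25),
    whiff = mk(bv_like, 0.25, crisp, -0.5),
    clue = mk(bv_like, 0.3, crisp, -0.5),
    discharge = mk(bv_like, 0.22, crisp, -0.4)
  )
}

#' Simulate a study cohort: sample metadata and taxon count matrix
#'
#' Draws BV status, race, community composition, sequencing counts, Nugent
#' scores and the four Amsel clinical signs for `n_samples` women.
#'
#' Non-BV communities are dominated by a Lactobacillus species (crispatus-
#' like with probability 0.6, iners-like otherwise) whose share always
#' exceeds 50%; BV communities are diverse, with log-normal abundances and
#' latent-factor-induced co-occurrence sub-groups. Counts come from a
#' zero-inflated negative binomial observation model (or exact multinomial
#' sampling, see [effect_config()]). The Nugent score decreases
#' logistically with the log Lactobacillus fraction; Amsel signs follow the
#' configured linear models on log counts, and `bv_amsel` applies the
#' 3-of-4 rule (pH > 4.5, positive whiff, any clue cells, abnormal
#' discharge).
#'
#' @param n_samples number of women.
#' @param frac_bv fraction assigned a BV-type community (in `[0, 1]`).
#' @param race_mix named probability vector over race labels.
#' @param taxa character vector of species taxids (typically the species of
#'   a [simulate_reference_world()] taxonomy).
#' @param config an [effect_config()].
#' @param seed integer seed.
#' @return list of class `cohort`: `meta` (tibble: `sample`, `bv` — the
#'   generative condition —, `race`, `nugent`, `bv_nugent`, `ph`,
#'   `amsel_whiff`, `clue_cells`, `amsel_discharge`, `bv_amsel`) and
#'   `counts` (tibble: `sample`, `taxid`, `count`, long form).
#' @export
simulate_cohort <- function(n_samples = 220, frac_bv = 0.445,
                            race_mix = c(Black = 0.34, White = 0.44, Other = 0.22),
                            taxa, config = effect_config(), seed = 1) {
  if (frac_bv < 0 || frac_bv > 1) stop("`frac_bv` must be in [0, 1]", call. = FALSE)
  if (length(race_mix) == 0) stop("`race_mix` must be non-empty", call. = FALSE)
  if (is.null(names(race_mix)) || any(!nzchar(names(race_mix)))) {
    stop("`race_mix` must be a named probability vector", call. = FALSE)
  }
  stopifnot(inherits(config, "effect_config"), length(taxa) >= 2)
  local_rng(seed)

  n_taxa <- length(taxa)
  lacto <- intersect(
    c("Lactobacillus_crispatus_like", "Lactobacillus_iners_like"), taxa
  )
  if (length(lacto) == 0) lacto <- taxa[1:2]
  subgroups <- config$subgroups %||% default_subgroups(taxa)
  sign_coefs <- config$sign_coefs %||% default_sign_coefs(taxa)

  sample_id <- sprintf("s%04d", seq_len(n_samples))
  bv <- stats::rbinom(n_samples, 1, frac_bv) == 1
  race <- factor(
    sample(names(race_mix), n_samples, replace = TRUE,
           prob = race_mix / sum(race_mix)),
    levels = names(race_mix)
  )

  # community composition, one row per sample
  comp <- matrix(0, n_samples, n_taxa, dimnames = list(sample_id, taxa))
  bv_mu <- rep(config$bv_meanlog, n_taxa)
  names(bv_mu) <- taxa
  # lactobacilli are depleted (but iners not absent) in BV communities
  if ("Lactobacillus_crispatus_like" %in% taxa) {
    bv_mu["Lactobacillus_crispatus_like"] <- config$bv_meanlog - 2.5
  }
  if ("Lactobacillus_iners_like" %in% taxa) {
    bv_mu["Lactobacillus_iners_like"] <- config$bv_meanlog - 0.5
  }
  for (i in seq_len(n_samples)) {
    if (bv[i]) {
      z <- bv_mu + stats::rnorm(n_taxa, 0, config$bv_sdlog)
      names(z) <- taxa
      for (g in subgroups) {
        z[g] <- z[g] + config$subgroup_loading * stats::rnorm(1)
      }
      w <- exp(z)
    } else {
      dom <- sample(lacto, 1, prob = if (length(lacto) == 2) c(0.6, 0.4) else NULL)
      share <- 0.5 + 0.5 * stats::rbeta(1, 0.8 * config$dominance_conc,
                                        0.2 * config$dominance_conc)
      rest <- stats::rgamma(n_taxa, shape = 0.3)
      names(rest) <- taxa
      # minor community members skew to the other lactobacilli
      rest[lacto] <- rest[lacto] * 4
      rest[dom] <- 0
      w <- rest / sum(rest) * (1 - share)
      w[dom] <- share
    }
    comp[i, ] <- w / sum(w)
  }

  # sequencing depth: log-normal with configured mean and CV
  sdlog <- sqrt(log(1 + config$depth_cv^2))
  meanlog <- log(config$depth_mean) - sdlog^2 / 2
  depth <- pmax(50, round(stats::rlnorm(n_samples, meanlog, sdlog)))

  # race-by-BV interaction multipliers on the count mean (first race level)
  interaction <- config$interaction %||% numeric(0)
  log_mult <- matrix(0, n_samples, n_taxa, dimnames = dimnames(comp))
  if (length(interaction)) {
    hit <- race == levels(race)[1] & bv
    for (t in names(interaction)) {
      if (t %in% taxa) log_mult[hit, t] <- interaction[[t]]
    }
  }

  counts <- matrix(0L, n_samples, n_taxa, dimnames = dimnames(comp))
  if (config$depth_model == "multinomial") {
    for (i in seq_len(n_samples)) {
      p <- comp[i, ] * exp(log_mult[i, ])
      counts[i, ] <- stats::rmultinom(1, depth[i], p / sum(p))[, 1]
    }
  } else {
    mu <- comp * depth * exp(log_mult)
    keep_zero <- matrix(stats::rbinom(length(mu), 1, config$pi) == 1, n_samples, n_taxa)
    y <- stats::rnbinom(length(mu), size = config$theta, mu = as.vector(mu))
    counts[] <- ifelse(keep_zero, 0L, as.integer(y))
    # In a Lactobacillus-dominated sample the dominant organism is neither a
    # dropout nor outnumbered: its count is set from the realised
    # non-dominant total so that it keeps its compositional share.
    for (i in which(!bv)) {
      dom <- which.max(comp[i, ])
      share <- comp[i, dom]
      rest <- sum(counts[i, -dom])
      counts[i, dom] <- max(1L, as.integer(round(rest * share / (1 - share))),
                            if (rest == 0) as.integer(round(share * depth[i])) else 0L)
    }
    # empty samples are not observed: give them their top taxon
    empty <- rowSums(counts) == 0
    if (any(empty)) {
      top <- max.col(comp[empty, , drop = FALSE])
      counts[cbind(which(empty), top)] <- pmax(
        1L, as.integer(stats::rnbinom(sum(empty), size = config$theta,
                                      mu = depth[empty] * 0.5))
      )
    }
  }

  # Nugent score: logistic decrease in the log Lactobacillus fraction
  lacto_frac <- rowSums(comp[, lacto, drop = FALSE])
  lf <- pmin(pmax(lacto_frac, 1e-6), 1 - 1e-6)
  nugent_latent <- stats::plogis(-0.9 * log(lf / (1 - lf)) + stats::rnorm(n_samples, 0, 0.6))
  nugent <- pmin(10L, pmax(0L, as.integer(round(10 * nugent_latent))))

  # Amsel signs from linear models on log(count + 0.5)
  logx <- log(counts + 0.5)
  sign_score <- function(coefs, center) {
    idx <- intersect(names(coefs), taxa)
    drop(logx[, idx, drop = FALSE] %*% coefs[idx]) - center
  }
  z_ph <- sign_score(sign_coefs$ph, stats::median(sign_score(sign_coefs$ph, 0)))
  ph <- round(pmin(7, pmax(3.5, 4.6 + 0.15 * z_ph + stats::rnorm(n_samples, 0, 0.25))), 1)
  z_whiff <- sign_score(sign_coefs$whiff, stats::median(sign_score(sign_coefs$whiff, 0)))
  amsel_whiff <- stats::rbinom(n_samples, 1, stats::plogis(0.8 * z_whiff)) == 1
  z_clue <- sign_score(sign_coefs$clue, stats::median(sign_score(sign_coefs$clue, 0)))
  clue_latent <- 0.8 * z_clue + stats::rnorm(n_samples, 0, 1)
  clue_cells <- cut(clue_latent, c(-Inf, 0, 1.2, Inf),
                    labels = c("none", "<20%", ">20%"))
  z_dis <- sign_score(sign_coefs$discharge,
                      stats::median(sign_score(sign_coefs$discharge, 0)))
  amsel_discharge <- stats::rbinom(n_samples, 1, stats::plogis(0.7 * z_dis)) == 1

  n_signs <- (ph > 4.5) + amsel_whiff + (clue_cells != "none") + amsel_discharge
  meta <- tibble::tibble(
    sample = sample_id,
    bv = bv,
    race = race,
    nugent = nugent,
    bv_nugent = nugent >= 7L,
    ph = as.numeric(ph),
    amsel_whiff = amsel_whiff,
    clue_cells = clue_cells,
    amsel_discharge = amsel_discharge,
    bv_amsel = n_signs >= 3L,
    depth = depth
  )
  counts_long <- tibble::as_tibble(as.data.frame.table(counts, stringsAsFactors = FALSE))
  names(counts_long) <- c("sample", "taxid", "count")
  counts_long$count <- as.integer(counts_long$count)
  counts_long <- dplyr::arrange(counts_long, .data$sample, .data$taxid)
  structure(list(meta = meta, counts = counts_long), class = "cohort")
}

#' Pivot a long count table to a sample-by-taxon integer matrix
#'
#' @param counts long tibble with columns `sample`, `taxid`, `count`.
#' @return integer matrix, samples in rows.
#' @export
count_matrix <- function(counts) {
  wide <- tidyr::pivot_wider(counts, names_from = "taxid",
                             values_from = "count", values_fill = 0L)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
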