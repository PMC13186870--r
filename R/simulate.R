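#' Additive-logistic disease model
#'
#' Risk of affection is `plogis(intercept + sum_j effect_j * g_j)` where
#' `g_j` is the alternate-allele count at causal variant `j`.  An empty
#' effect set defines the global null (affection independent of genotype).
#'
#' @param intercept Baseline log-odds of affection.  The default corresponds
#'   to a population prevalence of 0.33%, the multiple sclerosis prevalence
#'   reported for Sardinia.
#' @param effects Named or indexed numeric vector of per-allele log-odds
#'   increments; names/indices refer to variant column indices of the pool.
#' @return An object of class `triokf_disease_model`.
#' @examples
#' disease_model()                       # global null
#' disease_model(effects = c("120" = log(3)))
#' @export
disease_model <- function(intercept = qlogis(0.0033), effects = numeric()) {
  idx <- if (length(effects)) as.integer(names(effects) %||% seq_along(effects))
         else integer()
  if (length(effects) && anyNA(idx))
    abort("`effects` must be named by (or ordered as) variant column indices.")
  structure(list(intercept = intercept,
                 causal_idx = idx,
                 causal_beta = unname(as.numeric(effects))),
            class = "triokf_disease_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

risk_of <- function(model, dosage) {
  # dosage: matrix individuals x causal variants (aligned with causal_idx)
  eta <- model$intercept +
    if (length(model$causal_beta)) drop(dosage %*% model$causal_beta) else 0
  plogis(eta)
}

#' Simulate an ascertained phased trio cohort
#'
#' Draws parents as random founder haplotype pairs from the pool, forms
#' offspring haplotypes by Mendelian transmission with per-interval
#' recombination, assigns phenotypes from the disease model, and keeps only
#' families whose proband is affected (rejection sampling).  Two family
#' configurations are produced: type 1 families ascertain an affected
#' offspring; type 2 families ascertain an affected parent (the proband's
#' spouse and their child complete the trio, the child's phenotype is drawn
#' from the model, not forced).
#'
#' @param pool A `triokf_pool` from [build_haplotype_pool()].
#' @param n_type1,n_type2 Number of trios of each type (study sizes: 97 and
#'   60).
#' @param model A [disease_model()].
#' @param meiosis_recomb_per_bp Per-base-pair crossover probability used for
#'   transmitted haplotypes (default `1e-8`, about 1 cM/Mb).
#' @param single_parent_frac Fraction of type 1 families with one parent
#'   missing (duos); default 0.
#' @param max_attempts Rejection-sampling cap per family before erroring.
#' @param seed Integer seed.
#'
#' @return A list with elements `cohort` (a `triokf_cohort`) and `truth`
#'   (a `triokf_truth`): the ground-truth record holding, per trio and
#'   parent, the transmitted parental haplotype index at every variant, the
#'   causal model and the seed, sufficient to replay the cohort.
#' @examples
#' pool <- build_haplotype_pool(n_founders = 60, n_variants = 30,
#'                              region_end = 30920506, seed = 1)
#' sim <- simulate_trios(pool, n_type1 = 5, n_type2 = 3, seed = 2)
#' sim$cohort
#' @export
simulate_trios <- function(pool,
                           n_type1 = 97,
                           n_type2 = 60,
                           model = disease_model(),
                           meiosis_recomb_per_bp = 1e-8,
                           single_parent_frac = 0,
                           max_attempts = 10000L,
                           seed = 1L) {
  stopifnot(inherits(pool, "triokf_pool"))
  n_trio <- n_type1 + n_type2
  if (n_trio < 1) abort("at least one trio is required.")
  withr_seed(seed)

  H <- pool$haplotypes
  n_hap_pool <- nrow(H)
  V <- ncol(H)
  pos <- pool$variants$pos
  gap <- if (V > 1L) diff(pos) else integer()
  cross_p <- pmin(0.5, meiosis_recomb_per_bp * gap)
  cidx <- model$causal_idx
  if (length(cidx) && any(cidx < 1 | cidx > V))
    abort("causal variant index outside the pool.")

  # transmission path over variants for one meiosis, as run-length starts
  draw_path <- function() {
    t0 <- sample.int(2L, 1L)
    if (V == 1L) return(rep.int(t0, 1L))
    sw <- runif(V - 1L) < cross_p
    cumsum(c(t0 - 1L, sw)) %% 2L + 1L  # parity trick: switch flips 1<->2
  }

  p0 <- plogis(model$intercept)

  draw_trio <- function(type, duo) {
    if (!length(cidx)) {
      # global null: phenotypes are independent of genotype, so the
      # rejection loop only touches phenotypes
      if (runif(1L) < (1 - p0)^max_attempts)
        abort(paste0("ascertainment failed: no affected proband in ",
                     max_attempts, " attempts; the disease model makes ",
                     "affection too rare."))
      rows <- sample.int(n_hap_pool, 4L, replace = TRUE)
      pf <- draw_path()
      pm <- draw_path()
      fa <- H[rows[1:2], , drop = FALSE]
      mo <- H[rows[3:4], , drop = FALSE]
      off <- rbind(fa[cbind(pf, seq_len(V))], mo[cbind(pm, seq_len(V))])
      phen <- as.integer(runif(3L) < p0)
      names(phen) <- c("fa", "mo", "off")
      proband <- if (type == 1L) "off" else sample(c("fa", "mo"), 1L)
      phen[[proband]] <- 1L
      return(list(fa = fa, mo = mo, off = off, phen = phen,
                  proband = proband, path_f = pf, path_m = pm,
                  type = type, duo = duo))
    }
    for (attempt in seq_len(max_attempts)) {
      rows <- sample.int(n_hap_pool, 4L, replace = TRUE)  # f1 f2 m1 m2
      pf <- draw_path()
      pm <- draw_path()
      fa <- H[rows[1:2], , drop = FALSE]
      mo <- H[rows[3:4], , drop = FALSE]
      off <- rbind(fa[cbind(pf, seq_len(V))], mo[cbind(pm, seq_len(V))])
      g_cau <- function(m2) {
        if (!length(cidx)) matrix(0, 1, 0)
        else matrix(m2[1L, cidx] + m2[2L, cidx], 1L)
      }
      risk <- c(fa = risk_of(model, g_cau(fa)),
                mo = risk_of(model, g_cau(mo)),
                off = risk_of(model, g_cau(off)))
      phen <- as.integer(runif(3L) < risk)
      names(phen) <- c("fa", "mo", "off")
      proband <- if (type == 1L) "off" else sample(c("fa", "mo"), 1L)
      if (phen[[proband]] == 1L) {
        return(list(fa = fa, mo = mo, off = off, phen = phen,
                    proband = proband, path_f = pf, path_m = pm,
                    type = type, duo = duo))
      }
    }
    abort(paste0("ascertainment failed: no affected proband in ",
                 max_attempts, " attempts; the disease model makes ",
                 "affection too rare."))
  }

  types <- c(rep(1L, n_type1), rep(2L, n_type2))
  duos <- ifelse(types == 1L, runif(n_trio) < single_parent_frac, FALSE)
  trios <- lapply(seq_len(n_trio),
                  function(i) draw_trio(types[i], duos[i]))

  # assemble cohort
  trio_id <- sprintf("T%03d", seq_len(n_trio))
  ind <- list(); ped <- list()
  hap_list <- list()
  tr_f <- matrix(NA_integer_, n_trio, V)
  tr_m <- matrix(NA_integer_, n_trio, V)
  for (i in seq_len(n_trio)) {
    tr <- trios[[i]]
    drop_parent <- if (tr$duo) sample(c("fa", "mo"), 1L) else ""
    id_fa <- paste0(trio_id[i], "_fa")
    id_mo <- paste0(trio_id[i], "_mo")
    id_of <- paste0(trio_id[i], "_of")
    keep <- c(fa = drop_parent != "fa", mo = drop_parent != "mo", off = TRUE)
    if (keep[["fa"]]) {
      ind[[length(ind) + 1L]] <- tibble::tibble(id = id_fa, sex = 1L,
                                                phenotype = tr$phen[["fa"]])
      hap_list[[length(hap_list) + 1L]] <- tr$fa
      tr_f[i, ] <- tr$path_f
    }
    if (keep[["mo"]]) {
      ind[[length(ind) + 1L]] <- tibble::tibble(id = id_mo, sex = 2L,
                                                phenotype = tr$phen[["mo"]])
      hap_list[[length(hap_list) + 1L]] <- tr$mo
      tr_m[i, ] <- tr$path_m
    }
    ind[[length(ind) + 1L]] <- tibble::tibble(id = id_of, sex = 0L,
                                              phenotype = tr$phen[["off"]])
    hap_list[[length(hap_list) + 1L]] <- tr$off
    ped[[i]] <- tibble::tibble(
      trio_id = trio_id[i], trio_type = tr$type,
      father = if (keep[["fa"]]) id_fa else NA_character_,
      mother = if (keep[["mo"]]) id_mo else NA_character_,
      offspring = id_of,
      proband = switch(tr$proband, fa = id_fa, mo = id_mo, off = id_of)
    )
  }
  individuals <- dplyr::bind_rows(ind)
  pedigree <- dplyr::bind_rows(ped)
  haps <- do.call(rbind, hap_list)
  cohort <- new_cohort(haps, pool$variants, individuals, pedigree)

  truth <- structure(
    list(transmitted_father = tr_f, transmitted_mother = tr_m,
         trio_id = trio_id,
         causal_idx = model$causal_idx, causal_beta = model$causal_beta,
         intercept = model$intercept, seed = seed),
    class = "triokf_truth"
  )
  list(cohort = cohort, truth = truth)
}

#' @export
print.triokf_truth <- function(x, ...) {
  cat("<triokf_truth> ", length(x$trio_id), " trios, ",
      ncol(x$transmitted_father), " variants, ",
      length(x$causal_idx), " causal variants, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Inject uniform genotype missingness
#'
#' Sets a random fraction of (individual, variant) genotypes to missing
#' (both haplotype entries `NA`), to exercise quality control.
#'
#' @param cohort A `triokf_cohort`.
#' @param rate Per-genotype missingness probability.
#' @param seed Integer seed.
#' @return The cohort with missing entries injected.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(cohort)
  withr_seed(seed)
  n_ind <- nrow(cohort$individuals)
  V <- nrow(cohort$variants)
  miss <- matrix(runif(n_ind * V) < rate, n_ind, V)
  hm <- miss[rep(seq_len(n_ind), each = 2L), , drop = FALSE]
  cohort$haplotypes[hm] <- NA_integer_
  cohort
}
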