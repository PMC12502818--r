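# Synthetic family-cohort generator: pedigrees, NB count tables with
# planted disease effects, heritable taxa, community clusters, and
# biomarkers coupled to a latent dysbiosis score.

#' Build and validate a simulation configuration
#'
#' Defines the generative model for a synthetic family-based IBD cohort.
#' Per-sample taxon counts are drawn negative-binomially around a
#' compositional mean `softmax(baseline + disease_shift * dose + cluster
#' shift + genetic effect + compositional noise)` scaled by a log-normal
#' library size. The latent per-sample dysbiosis dose drives both the taxon
#' shifts and the biomarker panel.
#'
#' @param n_families Number of nuclear families.
#' @param family_templates Named probabilities over the nuclear-family
#'   templates `trio` (one child), `quad` (two children) and `quint`
#'   (three children).
#' @param n_taxa Number of taxa (ASVs).
#' @param library_size_meanlog,library_size_sdlog Log-normal library-size
#'   parameters (natural-log scale).
#' @param baseline_log_abundance Optional per-taxon baseline log-abundance
#'   vector; drawn from `N(0, 1.8)` when `NULL`.
#' @param dispersion Per-taxon NB size parameter (scalar or vector); drawn
#'   log-normally around 3 when `NULL`. Larger = less count noise.
#' @param disease_log2fc Optional per-taxon log2 fold change in IBD
#'   (positive = up in IBD). When `NULL`, 10% of taxa are spiked up
#'   (oral/Enterobacteriaceae-like, log2FC in U(1, 2.5)) and 10% down
#'   (SCFA-producer-like, U(-2.5, -1)).
#' @param ibd_prevalence Subject-level probability of IBD.
#' @param ibd_split Probabilities of CD/UC/uIBD within IBD subjects.
#' @param noise_sd Per-taxon SD of the compositional log-normal noise
#'   (scalar or vector; logistic-normal model only).
#' @param composition_model `"logistic_normal"` (default): per-sample
#'   compositions are `softmax` of the log-mean plus Gaussian noise;
#'   `"dirichlet"`: compositions are drawn from a Dirichlet centred on the
#'   softmax mean with total concentration `dirichlet_concentration`
#'   (matched to the Dirichlet-multinomial likelihood of community-type
#'   clustering).
#' @param dirichlet_concentration Total Dirichlet concentration (Dirichlet
#'   model only); smaller = more inter-sample variability.
#' @param dispersion_inflation_ibd Multiplier (>= 1) on the *variance* of
#'   the compositional noise in IBD samples; values above 1 produce the
#'   inflated inter-individual dispersion seen in IBD.
#' @param heritable_taxa Named vector mapping taxon index or id to a target
#'   narrow-sense heritability in `[0, 0.95]`; `NULL` plants h2 = 0.3 on 10%
#'   of non-disease taxa.
#' @param biomarker_coupling Named coefficients linking the latent dose to
#'   ASCA IgA/IgG, GP2 IgA/IgG, faecal calprotectin and Bristol stool score.
#' @param couplings Optional tibble `taxon_a, taxon_b, rho, condition`
#'   (condition in `all`, `IBD`, `Control`) planting pairwise correlations
#'   in the compositional noise; pairs must be disjoint.
#' @param n_clusters Number of planted community clusters (1 = none).
#' @param cluster_separation Minimum pairwise Aitchison distance between
#'   planted cluster centroids.
#' @param cluster_proportions Mixing proportions (default equal).
#' @param time_points Character vector of time points to simulate
#'   (independent redraws per time point).
#' @param include_prs Include weakly disease-coupled polygenic-risk-score
#'   columns in the metadata.
#' @param seed Integer seed; mandatory. Identical seed + config gives
#'   byte-identical output.
#' @return A `microfam_config` list.
#' @export
simulation_config <- function(n_families = 100,
                              family_templates = c(trio = 0.3, quad = 0.5, quint = 0.2),
                              n_taxa = 120,
                              library_size_meanlog = log(2e4),
                              library_size_sdlog = 0.35,
                              baseline_log_abundance = NULL,
                              dispersion = NULL,
                              disease_log2fc = NULL,
                              ibd_prevalence = 0.55,
                              ibd_split = c(CD = 0.54, UC = 0.43, uIBD = 0.03),
                              noise_sd = 0.7,
                              composition_model = c("logistic_normal", "dirichlet"),
                              dirichlet_concentration = 30,
                              dispersion_inflation_ibd = 2,
                              heritable_taxa = NULL,
                              biomarker_coupling = c(ASCA_IgA = 0.8, ASCA_IgG = 0.8,
                                                     GP2_IgA = 0.5, GP2_IgG = 0.5,
                                                     calprotectin = 1.2, BSS = 0.8),
                              couplings = NULL,
                              n_clusters = 1,
                              cluster_separation = 4,
                              cluster_proportions = NULL,
                              time_points = "BL",
                              include_prs = TRUE,
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  known <- c("trio", "quad", "quint")
  if (!all(names(family_templates) %in% known)) {
    abort(paste("unknown family template; use:", paste(known, collapse = ", ")))
  }
  if (n_families < 1) abort("`n_families` must be >= 1.")
  if (abs(sum(family_templates) - 1) > 1e-8) {
    family_templates <- family_templates / sum(family_templates)
  }
  if (!is.null(dispersion) && any(dispersion <= 0)) {
    abort("`dispersion` must be strictly positive.")
  }
  if (any(noise_sd <= 0)) abort("`noise_sd` must be strictly positive.")
  composition_model <- match.arg(composition_model)
  if (dirichlet_concentration <= 0) abort("`dirichlet_concentration` must be positive.")
  if (dispersion_inflation_ibd < 1) abort("`dispersion_inflation_ibd` must be >= 1.")
  if (ibd_prevalence < 0 || ibd_prevalence > 1) abort("`ibd_prevalence` must be in [0, 1].")
  if (library_size_sdlog <= 0) abort("library size sdlog must be positive.")
  if (!is.null(heritable_taxa) &&
      (any(heritable_taxa < 0) || any(heritable_taxa >= 0.95))) {
    abort("heritability targets must lie in [0, 0.95).")
  }
  if (!is.null(couplings) && any(abs(couplings$rho) >= 1)) {
    abort("coupling rho must be in (-1, 1).")
  }
  structure(list(
    n_families = as.integer(n_families),
    family_templates = family_templates,
    n_taxa = as.integer(n_taxa),
    library_size_meanlog = library_size_meanlog,
    library_size_sdlog = library_size_sdlog,
    baseline_log_abundance = baseline_log_abundance,
    dispersion = dispersion,
    disease_log2fc = disease_log2fc,
    ibd_prevalence = ibd_prevalence,
    ibd_split = ibd_split / sum(ibd_split),
    noise_sd = noise_sd,
    composition_model = composition_model,
    dirichlet_concentration = dirichlet_concentration,
    dispersion_inflation_ibd = dispersion_inflation_ibd,
    heritable_taxa = heritable_taxa,
    biomarker_coupling = biomarker_coupling,
    couplings = couplings,
    n_clusters = as.integer(n_clusters),
    cluster_separation = cluster_separation,
    cluster_proportions = cluster_proportions,
    time_points = time_points,
    include_prs = include_prs,
    seed = as.integer(seed)
  ), class = "microfam_config")
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

template_children <- c(trio = 1L, quad = 2L, quint = 3L)

ped_draw <- function(config) {
  tpl <- sample(names(config$family_templates), config$n_families,
                replace = TRUE, prob = config$family_templates)
  fam_ids <- sprintf("FAM%04d", seq_len(config$n_families))
  rows <- purrr::map2(fam_ids, tpl, function(fid, tp) {
    nk <- template_children[[tp]]
    fa <- paste0(fid, "_F")
    mo <- paste0(fid, "_M")
    kids <- paste0(fid, "_C", seq_len(nk))
    tibble::tibble(
      subject_id = c(fa, mo, kids),
      father_id = c(NA, NA, rep(fa, nk)),
      mother_id = c(NA, NA, rep(mo, nk)),
      sex = c("M", "F", sample(c("M", "F"), nk, replace = TRUE)),
      family_id = fid
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a pedigree of nuclear families
#'
#' @param config A [simulation_config()].
#' @return Pedigree tibble with columns `subject_id`, `father_id`,
#'   `mother_id`, `sex`, `family_id`; founders have `NA` parents.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "microfam_config"))
  with_seed(config$seed, ped_draw(config))
}

softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1, max))
  e / rowSums(e)
}

default_taxa <- function(config) {
  t_n <- config$n_taxa
  ids <- sprintf("ASV_%04d", seq_len(t_n))
  base <- config$baseline_log_abundance %||% sort(rnorm(t_n, 0, 1.8), decreasing = TRUE)
  if (length(base) != t_n) abort("baseline_log_abundance length must equal n_taxa.")
  disp <- config$dispersion %||% exp(rnorm(t_n, log(3), 0.5))
  disp <- rep_len(disp, t_n)
  n_up <- max(1L, floor(0.1 * t_n))
  lfc <- config$disease_log2fc
  if (is.null(lfc)) {
    lfc <- numeric(t_n)
    up <- seq_len(n_up)
    dn <- seq(t_n - n_up + 1L, t_n)
    lfc[up] <- runif(n_up, 1, 2.5)
    lfc[dn] <- runif(n_up, -2.5, -1)
  }
  if (length(lfc) != t_n) abort("disease_log2fc length must equal n_taxa.")
  taxonomy <- rep("Bacteria;Firmicutes;Clostridia", t_n)
  taxonomy[lfc > 0] <- "Bacteria;Proteobacteria;Enterobacteriaceae_or_oral"
  taxonomy[lfc < 0] <- "Bacteria;Firmicutes;SCFA_producer"
  h2 <- rep(0, t_n)
  if (is.null(config$heritable_taxa)) {
    idle <- which(lfc == 0)
    nh <- max(1L, floor(0.1 * t_n))
    h2[idle[seq_len(min(nh, length(idle)))]] <- 0.3
  } else {
    ht <- config$heritable_taxa
    idx <- if (!is.null(names(ht)) && all(names(ht) %in% ids)) {
      match(names(ht), ids)
    } else {
      as.integer(names(ht) %||% seq_along(ht))
    }
    h2[idx] <- unname(ht)
  }
  nsd <- rep_len(config$noise_sd, t_n)
  list(ids = ids, baseline = base, dispersion = disp, log2fc = lfc,
       h2 = h2, noise_sd = nsd, taxonomy = setNames(taxonomy, ids))
}

cluster_centroids <- function(config, t_n) {
  k <- config$n_clusters
  if (k <= 1) return(matrix(0, 1, t_n))
  d <- matrix(rnorm(k * t_n), k, t_n)
  d <- d - rowMeans(d)
  dd <- as.matrix(dist(d))
  scale <- config$cluster_separation / min(dd[upper.tri(dd)])
  d * scale
}

# Correlate the compositional noise via a Gaussian copula whose
# correlation graph is given by the coupling rows active for each
# condition; near-singular matrices are ridge-bent back to PD.
coupling_chol <- function(couplings, taxa_ids, group) {
  t_n <- length(taxa_ids)
  S <- diag(t_n)
  rows <- couplings[(couplings$condition %||% "all") %in% c("all", group), , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  for (i in seq_len(nrow(rows))) {
    a <- match(rows$taxon_a[i], taxa_ids)
    b <- match(rows$taxon_b[i], taxa_ids)
    if (is.na(a) || is.na(b)) abort("coupled taxon not found in taxon ids.")
    S[a, b] <- S[b, a] <- rows$rho[i]
  }
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-6) {
    w <- (1 - 1e-3) / (1 - min(ev, 0) + 1e-3)
    S <- w * S + (1 - w) * diag(t_n)
  }
  chol(S)
}

apply_couplings <- function(eps, couplings, diag_ibd, taxa_ids) {
  if (is.null(couplings)) return(eps)
  for (grp in c("IBD", "Control")) {
    rows <- if (grp == "IBD") diag_ibd else !diag_ibd
    if (!any(rows)) next
    L <- coupling_chol(couplings, taxa_ids, grp)
    if (!is.null(L)) eps[rows, ] <- eps[rows, , drop = FALSE] %*% L
  }
  eps
}

#' Simulate a synthetic family IBD cohort
#'
#' Draws a pedigree, subject diagnoses, latent per-sample dysbiosis doses,
#' kinship-correlated genetic effects for heritable taxa, compositional
#' noise (inflated in IBD), planted community clusters, NB counts and a
#' biomarker panel. See [simulation_config()] for the model.
#'
#' @param config A [simulation_config()].
#' @return A `microfam_cohort` list with elements `counts` (wide count
#'   tibble), `metadata`, `pedigree`, `truth` (planted log2FC, h2 targets,
#'   cluster labels, latent dysbiosis dose) and `taxonomy`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "microfam_config"))
  with_seed(config$seed, {
    ped <- ped_draw(config)
    n_s <- nrow(ped)
    taxa <- default_taxa(config)
    t_n <- config$n_taxa

    ibd <- rbinom(n_s, 1, config$ibd_prevalence) == 1
    diagnosis <- rep("Control", n_s)
    diagnosis[ibd] <- sample(names(config$ibd_split), sum(ibd),
                             replace = TRUE, prob = config$ibd_split)

    # genetic effects: one MVN draw per heritable taxon, covariance sg2 * A
    g <- matrix(0, n_s, t_n)
    her <- which(taxa$h2 > 0)
    if (length(her) > 0) {
      A <- kinship_matrix(ped)
      Am <- A$matrix[ped$subject_id, ped$subject_id]
      L <- chol(Am + diag(1e-8, n_s))
      for (t in her) {
        sg <- sqrt(taxa$h2[t] / (1 - taxa$h2[t])) * taxa$noise_sd[t]
        g[, t] <- sg * drop(crossprod(L, rnorm(n_s)))
      }
    }

    cent <- cluster_centroids(config, t_n)
    props <- config$cluster_proportions %||% rep(1 / config$n_clusters, config$n_clusters)

    meta_rows <- list(); count_rows <- list(); truth_rows <- list()
    age <- ifelse(is.na(ped$father_id), rnorm(n_s, 52, 8), rnorm(n_s, 26, 6))
    age <- pmin(pmax(age, 18), 85)
    bmi <- pmin(pmax(rnorm(n_s, 25.5, 4), 16), 45)

    for (tp in config$time_points) {
      smp <- if (length(config$time_points) == 1 && tp == "BL") {
        ped$subject_id
      } else paste0(ped$subject_id, "_", tp)
      dose <- pmax(as.numeric(ibd) + rnorm(n_s, 0, 0.25), 0)
      cl <- sample.int(config$n_clusters, n_s, replace = TRUE, prob = props)
      infl <- ifelse(ibd, sqrt(config$dispersion_inflation_ibd), 1)
      eta <- matrix(taxa$baseline, n_s, t_n, byrow = TRUE) +
        (log(2) * dose) %o% taxa$log2fc + cent[cl, , drop = FALSE] + g
      if (config$composition_model == "logistic_normal") {
        eps <- matrix(rnorm(n_s * t_n), n_s, t_n)
        eps <- apply_couplings(eps, config$couplings, ibd, taxa$ids)
        eps <- eps * (infl %o% taxa$noise_sd)
        p <- softmax_rows(eta + eps)
      } else {
        # Dirichlet around the softmax mean; IBD inflation lowers the
        # concentration (more inter-individual spread)
        conc <- config$dirichlet_concentration / infl^2
        am <- softmax_rows(eta) * conc
        p <- matrix(rgamma(n_s * t_n, shape = am), n_s, t_n)
        p <- p / rowSums(p)
      }
      lib <- rlnorm(n_s, config$library_size_meanlog, config$library_size_sdlog)
      mu <- p * lib
      cnt <- matrix(rnbinom(n_s * t_n,
                            size = rep(taxa$dispersion, each = n_s),
                            mu = mu),
                    n_s, t_n, dimnames = list(smp, taxa$ids))

      z <- dose
      bc <- config$biomarker_coupling
      meta_rows[[tp]] <- tibble::tibble(
        sample_id = smp,
        subject_id = ped$subject_id,
        family_id = ped$family_id,
        time_point = tp,
        diagnosis = diagnosis,
        age = round(age, 1),
        sex = ped$sex,
        bmi = round(bmi, 1),
        ASCA_IgA = exp(2 + bc[["ASCA_IgA"]] * z + rnorm(n_s, 0, 0.5)),
        ASCA_IgG = exp(2 + bc[["ASCA_IgG"]] * z + rnorm(n_s, 0, 0.5)),
        GP2_IgA = exp(1.5 + bc[["GP2_IgA"]] * z + rnorm(n_s, 0, 0.5)),
        GP2_IgG = exp(1.5 + bc[["GP2_IgG"]] * z + rnorm(n_s, 0, 0.5)),
        calprotectin = exp(3 + bc[["calprotectin"]] * z + rnorm(n_s, 0, 0.6)),
        BSS = pmin(pmax(round(3.5 + bc[["BSS"]] * z + rnorm(n_s, 0, 0.9)), 1), 7)
      )
      if (config$include_prs) {
        meta_rows[[tp]]$CD_PRS <- 0.4 * (diagnosis == "CD") + rnorm(n_s)
        meta_rows[[tp]]$UC_PRS <- 0.4 * (diagnosis == "UC") + rnorm(n_s)
        meta_rows[[tp]]$IBD_PRS <- 0.4 * ibd + rnorm(n_s)
      }
      count_rows[[tp]] <- cnt
      truth_rows[[tp]] <- tibble::tibble(sample_id = smp, cluster = cl, dysbiosis = z)
    }

    counts <- do.call(rbind, count_rows)
    metadata <- dplyr::bind_rows(meta_rows)
    metadata$diagnosis <- factor(metadata$diagnosis,
                                 levels = c("Control", "CD", "UC", "uIBD"))
    metadata$time_point <- factor(metadata$time_point, levels = config$time_points)
    metadata$sex <- factor(metadata$sex, levels = c("F", "M"))
    truth <- list(
      log2fc = setNames(taxa$log2fc, taxa$ids),
      h2 = setNames(taxa$h2, taxa$ids),
      baseline = setNames(taxa$baseline, taxa$ids),
      dispersion = setNames(taxa$dispersion, taxa$ids),
      noise_sd = setNames(taxa$noise_sd, taxa$ids),
      clusters = dplyr::bind_rows(truth_rows)[c("sample_id", "cluster")],
      dysbiosis = dplyr::bind_rows(truth_rows)[c("sample_id", "dysbiosis")]
    )
    structure(list(counts = count_tbl(counts), metadata = metadata,
                   pedigree = ped, truth = truth, taxonomy = taxa$taxonomy,
                   config = config),
              class = "microfam_cohort")
  })
}

#' @export
print.microfam_cohort <- function(x, ...) {
  m <- count_matrix(x$counts)
  cat("<microfam_cohort> ", nrow(m), " samples x ", ncol(m), " taxa; ",
      length(unique(x$pedigree$family_id)), " families\n", sep = "")
  print(table(x$metadata$diagnosis))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes `counts.tsv`, `metadata.tsv`, `pedigree.tsv` (founder parents as
#' empty strings), `truth.json` and optionally `counts.biom` (BIOM v1 JSON)
#' into `dir`.
#'
#' @param cohort A `microfam_cohort`.
#' @param dir Output directory (created if needed).
#' @param biom Also write BIOM v1.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, biom = FALSE) {
  stopifnot(inherits(cohort, "microfam_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  ped <- cohort$pedigree
  ped$father_id[is.na(ped$father_id)] <- ""
  ped$mother_id[is.na(ped$mother_id)] <- ""
  readr::write_tsv(ped, file.path(dir, "pedigree.tsv"), progress = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(log2fc = as.list(truth$log2fc), h2 = as.list(truth$h2),
         clusters = truth$clusters, dysbiosis = truth$dysbiosis),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  if (biom) write_counts_biom(cohort$counts, file.path(dir, "counts.biom"))
  invisible(dir)
}
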