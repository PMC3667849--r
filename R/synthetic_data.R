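#' Configuration for the synthetic study generator
#'
#' Defaults emulate the structure of the motivating study design: 26
#' chemicals (about half hepatocarcinogens) given at a single MTD-style dose
#' to small treated/control groups, a ~200-pathway panel shared across
#' species, and two-year-bioassay-style tumor outcomes with poly-3 survival
#' adjustment.
#'
#' @param seed master integer seed; every derived quantity is deterministic
#'   given it.
#' @param n_genes size of the measured gene universe (default 4000).
#' @param n_pathways number of pathways (default 200).
#' @param pathway_size_range inclusive node-count range per pathway
#'   (default 10-80; draws overlap in the gene universe).
#' @param n_chemicals number of chemicals (default 26).
#' @param n_causal_pathways number of causal pathways driving
#'   carcinogenicity (default 5, shared by all carcinogens).
#' @param delta expression shift, log2 units, on causal-pathway genes of
#'   carcinogens (default 1.0).
#' @param sigma within-group gene noise SD, log2 units (default 1.0).
#' @param animals_per_group expression-study animals per arm (default 4).
#' @param terminus_bias extra shift fraction on the terminal half of each
#'   causal pathway (default 0.5: those genes shift by `delta * 1.5`).
#' @param species character vector; the first entry is the reference
#'   species whose data train the model (default mouse, rat, human).
#' @param ortholog_noise fraction of genes re-drawn (orthology broken) per
#'   non-reference species (default 0.1).
#' @param q0 control-arm tumor probability (default 0.2).
#' @param gamma logistic gain linking mean causal-pathway shift to treated
#'   tumor probability (default 1.5).
#' @param bioassay_n animals per bioassay arm (default 50).
#' @param death_fraction fraction of tumor-free animals dying before
#'   terminal sacrifice (default 0.2).
#' @param death_window death-time window, as study fraction, for early
#'   tumor-free deaths (default `c(0.4, 1)`).
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_genes = 4000L, n_pathways = 200L,
                             pathway_size_range = c(10L, 80L),
                             n_chemicals = 26L, n_causal_pathways = 5L,
                             delta = 1.0, sigma = 1.0,
                             animals_per_group = 4L, terminus_bias = 0.5,
                             species = c("mouse", "rat", "human"),
                             ortholog_noise = 0.1, q0 = 0.2, gamma = 1.5,
                             bioassay_n = 50L, death_fraction = 0.2,
                             death_window = c(0.4, 1)) {
  cfg <- list(seed = seed, n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_chemicals = as.integer(n_chemicals),
              n_causal_pathways = as.integer(n_causal_pathways),
              delta = delta, sigma = sigma,
              animals_per_group = as.integer(animals_per_group),
              terminus_bias = terminus_bias, species = species,
              ortholog_noise = ortholog_noise, q0 = q0, gamma = gamma,
              bioassay_n = as.integer(bioassay_n),
              death_fraction = death_fraction, death_window = death_window)
  with(cfg, {
    stopifnot(n_genes > 0L, n_pathways > 0L, n_chemicals > 0L,
              length(pathway_size_range) == 2L,
              pathway_size_range[1L] >= 2L,
              pathway_size_range[2L] <= n_genes,
              pathway_size_range[1L] <= pathway_size_range[2L],
              n_causal_pathways >= 0L, n_causal_pathways <= n_pathways,
              delta >= 0, sigma >= 0, animals_per_group >= 2L,
              terminus_bias >= 0, length(species) >= 1L,
              ortholog_noise >= 0, ortholog_noise <= 1,
              q0 >= 0, q0 <= 1, bioassay_n >= 1L,
              death_fraction >= 0, death_fraction <= 1,
              length(death_window) == 2L, death_window[1L] > 0,
              death_window[2L] <= 1)
  })
  structure(cfg, class = "generator_config")
}

# Preferential-attachment skeleton over `genes`, with `n_term` terminus
# (root) nodes. Each later node sends one directed edge toward an earlier
# node chosen proportionally to in-degree + 1, so signal flows toward the
# roots, which are the only out-degree-0 nodes. A few extra shortcut edges
# (from non-roots to earlier nodes) make the graph connected-ish without
# creating new termini.
pa_pathway <- function(pathway_id, species, genes, n_term) {
  n <- length(genes)
  n_term <- max(1L, min(n_term, n %/% 2L))
  indeg <- rep(0L, n)
  edges <- matrix(character(), ncol = 2L)
  if (n > n_term) {
    src <- integer(n - n_term)
    dst <- integer(n - n_term)
    for (j in seq.int(n_term + 1L, n)) {
      # the first node after the roots anchors each root so no root is
      # isolated; later nodes attach preferentially by in-degree
      tgt <- if (j <= 2L * n_term) {
        j - n_term
      } else {
        sample.int(j - 1L, 1L, prob = indeg[seq_len(j - 1L)] + 1)
      }
      src[j - n_term] <- j
      dst[j - n_term] <- tgt
      indeg[tgt] <- indeg[tgt] + 1L
    }
    edges <- cbind(genes[src], genes[dst])
    n_extra <- max(0L, round(0.1 * n))
    for (k in seq_len(n_extra)) {
      u <- sample.int(n - n_term, 1L) + n_term
      v <- sample.int(u - 1L, 1L)
      if (v != u) edges <- rbind(edges, c(genes[u], genes[v]))
    }
  }
  pathway_network(pathway_id, species, nodes = genes, edges = edges)
}

#' Generate per-species pathway collections and an orthology map
#'
#' Builds `n_pathways` random directed pathways (preferential-attachment
#' skeletons, 1-3 terminus nodes each) over the reference gene universe.
#' Non-reference species receive topologically identical copies in which an
#' `ortholog_noise` fraction of genes is re-drawn as species-private genes
#' with no ortholog, emulating annotation mismatch; the remaining genes map
#' to the reference gene as their canonical ortholog. The shared panel is
#' all pathways.
#'
#' @param config a [generator_config()].
#' @return list of class `pathway_db`: `collections` (per species, named
#'   lists of [pathway_network()]), `orthology` ([orthology_map()]),
#'   `panel`, `universes` (per species: reference gene -> species gene),
#'   `terminal_half` (per pathway: reference genes in the terminal half,
#'   used by the study generator), `reference`.
#' @export
generate_pathway_db <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  local_seed(config$seed, {
    universe <- sprintf("g%04d", seq_len(config$n_genes))
    ref <- config$species[[1L]]
    ids <- sprintf("P%03d", seq_len(config$n_pathways))
    ref_nets <- stats::setNames(vector("list", length(ids)), ids)
    for (i in seq_along(ids)) {
      size <- sample(seq.int(config$pathway_size_range[1L],
                             config$pathway_size_range[2L]), 1L)
      genes <- sample(universe, size)
      ref_nets[[i]] <- pa_pathway(ids[i], ref, genes, sample(1:3, 1L))
    }
    terminal_half <- lapply(ref_nets, function(net) {
      d <- terminus_distance(net)
      fin <- d[is.finite(d)]
      names(fin)[fin <= stats::median(fin)]
    })
    universes <- list()
    universes[[ref]] <- stats::setNames(universe, universe)
    collections <- list()
    collections[[ref]] <- ref_nets
    orth <- data.frame(species = ref, gene = universe, canonical = universe,
                       stringsAsFactors = FALSE)
    for (sp in setdiff(config$species, ref)) {
      broken <- stats::runif(config$n_genes) < config$ortholog_noise
      sp_gene <- ifelse(broken, paste0(sp, "_x", universe),
                        paste0(sp, "_", universe))
      canonical <- ifelse(broken, sp_gene, universe)
      map <- stats::setNames(sp_gene, universe)
      universes[[sp]] <- map
      collections[[sp]] <- lapply(ref_nets, function(net) {
        e <- net$edges
        if (nrow(e) > 0L) e <- matrix(map[e], ncol = 2L)
        pathway_network(net$pathway_id, sp, nodes = unname(map[net$nodes]),
                        edges = e)
      })
      orth <- rbind(orth, data.frame(species = sp, gene = sp_gene,
                                     canonical = canonical,
                                     stringsAsFactors = FALSE))
    }
    structure(list(collections = collections,
                   orthology = orthology_map(orth),
                   panel = shared_panel(collections),
                   universes = universes,
                   terminal_half = terminal_half,
                   reference = ref),
              class = "pathway_db")
  })
}

# Per-chemical reference-gene shift vector. Causal-pathway genes shift by
# delta * multiplier; genes in the terminal half of a causal pathway by an
# extra (1 + terminus_bias) factor. Genes in several causal pathways take
# the maximum shift.
chemical_shift <- function(config, db, causal, multiplier) {
  shift <- numeric(0)
  if (multiplier == 0) return(shift)
  for (pid in causal) {
    net <- db$collections[[db$reference]][[pid]]
    s <- rep(config$delta * multiplier, length(net$nodes))
    names(s) <- net$nodes
    th <- intersect(db$terminal_half[[pid]], net$nodes)
    s[th] <- s[th] * (1 + config$terminus_bias)
    new <- setdiff(names(s), names(shift))
    shift[new] <- 0
    shift[names(s)] <- pmax(shift[names(s)], s)
  }
  shift
}

#' Generate a complete synthetic study with known ground truth
#'
#' Half the chemicals (rounded up) are carcinogens. Each carcinogen shifts
#' the genes of the shared causal pathways in its treated animals (terminal
#' halves more strongly), with a chemical-specific potency multiplier drawn
#' uniformly from 0.5-1.5 so the continuous target varies. All expression
#' values sit on a Normal(7, 1) per-gene baseline with Normal(0, sigma)
#' noise. Tumor outcomes are drawn per animal: controls at rate `q0`,
#' treated at `plogis(qlogis(q0) + gamma * m)` where `m` is the chemical's
#' mean causal-pathway shift; early tumor-free deaths get poly-3 fractional
#' weights via [poly3_adjusted_counts()].
#'
#' @param config a [generator_config()].
#' @param db optional [generate_pathway_db()] result (generated from
#'   `config` when omitted).
#' @return list of class `ground_truth`: `config`, `db`, `chemicals` (data
#'   frame: id, carcinogen flag, potency multiplier, mean shift `m`, true
#'   tumor probabilities), `causal_pathways`, `studies` (named list of
#'   reference-species [expression_study()]), `bioassay` (named list of
#'   [bioassay_record()]).
#' @export
generate_study <- function(config, db = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(db)) db <- generate_pathway_db(config)
  local_seed(config$seed + 1L, {
    n <- config$n_chemicals
    ids <- sprintf("chem%02d", seq_len(n))
    carcinogen <- seq_len(n) <= ceiling(n / 2)
    causal <- sort(sample(db$panel, config$n_causal_pathways))
    multiplier <- ifelse(carcinogen, stats::runif(n, 0.5, 1.5), 0)
    universe <- names(db$universes[[db$reference]])
    mu <- stats::rnorm(length(universe), mean = 7, sd = 1)
    names(mu) <- universe
    a <- config$animals_per_group
    studies <- stats::setNames(vector("list", n), ids)
    bioassay <- stats::setNames(vector("list", n), ids)
    m_val <- numeric(n)
    p_treat_true <- numeric(n)
    for (i in seq_len(n)) {
      shift <- chemical_shift(config, db, causal, multiplier[i])
      vals <- matrix(stats::rnorm(length(universe) * 2L * a, sd = config$sigma),
                     nrow = length(universe))
      vals <- vals + mu
      rownames(vals) <- universe
      colnames(vals) <- c(paste0(ids[i], "_c", seq_len(a)),
                          paste0(ids[i], "_t", seq_len(a)))
      groups <- rep(c("control", "treated"), each = a)
      if (length(shift) > 0L) {
        vals[names(shift), groups == "treated"] <-
          vals[names(shift), groups == "treated"] + shift
      }
      studies[[i]] <- expression_study(vals, groups)
      causal_genes <- unique(unlist(lapply(causal, function(pid)
        db$collections[[db$reference]][[pid]]$nodes)))
      m_val[i] <- if (length(shift) > 0L) {
        mean(shift[causal_genes])
      } else 0
      p_treat_true[i] <- stats::plogis(stats::qlogis(config$q0) +
                                         config$gamma * m_val[i])
      bioassay[[i]] <- simulate_bioassay(ids[i], p_treat_true[i], config)
    }
    structure(list(config = config, db = db,
                   chemicals = data.frame(chemical_id = ids,
                                          carcinogen = carcinogen,
                                          multiplier = multiplier,
                                          m = m_val,
                                          p_treat_true = p_treat_true,
                                          p_cont_true = config$q0,
                                          stringsAsFactors = FALSE),
                   causal_pathways = causal,
                   studies = studies,
                   bioassay = bioassay),
              class = "ground_truth")
  })
}

# Per-animal tumor outcomes and poly-3 adjustment for one chemical.
# Assumes the RNG state of the caller (generate_study).
simulate_bioassay <- function(chemical_id, p_treat, config) {
  draw_arm <- function(p) {
    tumor <- stats::runif(config$bioassay_n) < p
    t <- rep(1, config$bioassay_n)
    early <- !tumor & stats::runif(config$bioassay_n) < config$death_fraction
    t[early] <- stats::runif(sum(early), config$death_window[1L],
                             config$death_window[2L])
    poly3_adjusted_counts(t, tumor)
  }
  treat <- draw_arm(p_treat)
  cont <- draw_arm(config$q0)
  bioassay_record(chemical_id, n_treat = treat$n_adj, p_treat = treat$p_adj,
                  n_cont = cont$n_adj, p_cont = cont$p_adj)
}

#' Generate the expression panel for a non-reference species
#'
#' Re-uses each chemical's carcinogen flag, causal pathways and potency, but
#' draws fresh animals in the target species' gene space. Genes whose
#' orthology was broken by the generator receive no shift (their causal
#' signal is lost), which is exactly the annotation mismatch that degrades
#' cross-species extrapolation.
#'
#' @param truth a `ground_truth` from [generate_study()].
#' @param species target species token (must be in the config's species
#'   list, other than the reference).
#' @return list of class `species_panel`: `species`, `studies` (named list
#'   of [expression_study()] in species gene space), `labels` (named
#'   character, `"positive"` for carcinogens), `collection` (the species'
#'   pathway networks).
#' @export
generate_cross_species_panel <- function(truth, species) {
  stopifnot(inherits(truth, "ground_truth"))
  config <- truth$config
  db <- truth$db
  if (!species %in% config$species) {
    stop("unknown species token '", species, "'; configured species: ",
         paste(config$species, collapse = ", "))
  }
  sp_index <- match(species, config$species)
  map <- db$universes[[species]]           # reference gene -> species gene
  local_seed(config$seed + 1000L * sp_index, {
    sp_universe <- unname(map)
    mu <- stats::rnorm(length(sp_universe), mean = 7, sd = 1)
    names(mu) <- sp_universe
    a <- config$animals_per_group
    ids <- truth$chemicals$chemical_id
    studies <- stats::setNames(vector("list", length(ids)), ids)
    conserved <- db$orthology$gene[db$orthology$species == species &
                                     db$orthology$canonical %in% names(map)]
    for (i in seq_along(ids)) {
      shift_ref <- chemical_shift(config, db, truth$causal_pathways,
                                  truth$chemicals$multiplier[i])
      vals <- matrix(stats::rnorm(length(sp_universe) * 2L * a,
                                  sd = config$sigma),
                     nrow = length(sp_universe))
      vals <- vals + mu
      rownames(vals) <- sp_universe
      colnames(vals) <- c(paste0(ids[i], "_c", seq_len(a)),
                          paste0(ids[i], "_t", seq_len(a)))
      groups <- rep(c("control", "treated"), each = a)
      if (length(shift_ref) > 0L) {
        sp_shift <- shift_ref
        names(sp_shift) <- map[names(shift_ref)]
        # only species genes that remained orthologous carry the signal
        sp_shift <- sp_shift[names(sp_shift) %in% conserved]
        if (length(sp_shift) > 0L) {
          vals[names(sp_shift), groups == "treated"] <-
            vals[names(sp_shift), groups == "treated"] + sp_shift
        }
      }
      studies[[i]] <- expression_study(vals, groups)
    }
    structure(list(species = species, studies = studies,
                   labels = stats::setNames(
                     ifelse(truth$chemicals$carcinogen, "positive", "negative"),
                     ids),
                   collection = db$collections[[species]]),
              class = "species_panel")
  })
}

#' Generate a dose-series expression set for selected chemicals
#'
#' Scales each chemical's expression shift by a dose fraction, emulating a
#' multi-dose 90-day design on top of the single-MTD default; the top
#' fraction (1.0) reproduces the main study's condition.
#'
#' @param truth a `ground_truth`.
#' @param chemical_ids chemicals to expand (default: first 2 carcinogens
#'   and first non-carcinogen).
#' @param dose_fracs increasing dose fractions of the MTD
#'   (default `c(0.1, 0.25, 0.5, 0.75, 1)`).
#' @return list per chemical: `doses` (fractions) and `studies` (one
#'   [expression_study()] per dose).
#' @export
generate_dose_series <- function(truth, chemical_ids = NULL,
                                 dose_fracs = c(0.1, 0.25, 0.5, 0.75, 1)) {
  stopifnot(inherits(truth, "ground_truth"), all(diff(dose_fracs) > 0))
  config <- truth$config
  db <- truth$db
  if (is.null(chemical_ids)) {
    carc <- truth$chemicals$chemical_id[truth$chemicals$carcinogen]
    noncarc <- truth$chemicals$chemical_id[!truth$chemicals$carcinogen]
    chemical_ids <- c(utils::head(carc, 2L), utils::head(noncarc, 1L))
  }
  stopifnot(all(chemical_ids %in% truth$chemicals$chemical_id))
  universe <- names(db$universes[[db$reference]])
  local_seed(config$seed + 77L, {
    mu <- stats::rnorm(length(universe), mean = 7, sd = 1)
    names(mu) <- universe
    a <- config$animals_per_group
    out <- stats::setNames(vector("list", length(chemical_ids)), chemical_ids)
    for (cid in chemical_ids) {
      i <- match(cid, truth$chemicals$chemical_id)
      studies <- stats::setNames(vector("list", length(dose_fracs)),
                                 paste0("dose", seq_along(dose_fracs)))
      for (d in seq_along(dose_fracs)) {
        shift <- chemical_shift(config, db, truth$causal_pathways,
                                truth$chemicals$multiplier[i] * dose_fracs[d])
        vals <- matrix(stats::rnorm(length(universe) * 2L * a,
                                    sd = config$sigma),
                       nrow = length(universe)) + mu
        rownames(vals) <- universe
        colnames(vals) <- c(paste0(cid, "_c", seq_len(a)),
                            paste0(cid, "_t", seq_len(a)))
        groups <- rep(c("control", "treated"), each = a)
        if (length(shift) > 0L) {
          vals[names(shift), groups == "treated"] <-
            vals[names(shift), groups == "treated"] + shift
        }
        studies[[d]] <- expression_study(vals, groups)
      }
      out[[cid]] <- list(doses = dose_fracs, studies = studies)
    }
    out
  })
}
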