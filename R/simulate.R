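# Synthetic two-group cohorts with implanted topological group differences.
#
# The generator emulates what the downstream pipeline actually consumes:
# per-subject multivariate-normal ROI series whose correlation matrix is
# built from a modular "generating graph" (edges carry correlation r_edge,
# non-edges a weak background r_background). A group effect is a specified
# alteration of group 2's generating graph — densifying one module (raises
# clustering of its nodes) or rewiring a hub across modules (raises its
# betweenness/participation) — so ground truth about which nodes and
# metrics differ is known exactly.

#' Configuration for a synthetic two-group cohort
#'
#' @param n_rois Number of ROIs (network nodes).
#' @param t_timepoints Time points per subject. `t_timepoints >= 2 * n_rois`
#'   is recommended; shorter series (as in real resting-state cohorts) are
#'   allowed with a warning.
#' @param n_per_group Subjects per group (group 1 = HC, group 2 = ASD).
#' @param module_sizes Integer vector of module sizes summing to `n_rois`;
#'   default four near-equal modules.
#' @param p_within,p_between Edge probabilities of the generating graph
#'   within and between modules.
#' @param r_edge Target correlation on generating-graph edges.
#' @param r_background Baseline correlation on non-edges.
#' @param jitter_sd SD of symmetric subject-level perturbation added to the
#'   group correlation matrix (individual variability).
#' @param effect Effect specification from [effect_spec()], or `NULL` for a
#'   null (zero-effect) cohort where both groups share one generating graph.
#' @param seed Integer RNG seed (mandatory; the whole cohort is a
#'   deterministic function of the config).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_rois = 16, t_timepoints = 150,
                              n_per_group = 30, module_sizes = NULL,
                              p_within = 0.85, p_between = 0.05,
                              r_edge = 0.35, r_background = 0.03,
                              jitter_sd = 0.02, effect = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  if (is.null(module_sizes)) {
    k <- min(4, max(2, n_rois %/% 4))
    base <- n_rois %/% k
    module_sizes <- rep(base, k)
    module_sizes[seq_len(n_rois - base * k)] <-
      module_sizes[seq_len(n_rois - base * k)] + 1
  }
  if (sum(module_sizes) != n_rois) {
    stop("`module_sizes` must sum to `n_rois`.", call. = FALSE)
  }
  probs <- c(p_within, p_between)
  if (any(probs < 0 | probs > 1)) {
    stop("Edge probabilities must be in [0, 1].", call. = FALSE)
  }
  if (t_timepoints < 2 * n_rois) {
    warning("t_timepoints < 2 * n_rois: short series give noisy ",
      "connectivity estimates (as in real resting-state data).",
      call. = FALSE
    )
  }
  structure(
    list(
      n_rois = n_rois, t_timepoints = t_timepoints,
      n_per_group = n_per_group, module_sizes = module_sizes,
      p_within = p_within, p_between = p_between, r_edge = r_edge,
      r_background = r_background, jitter_sd = jitter_sd, effect = effect,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Specify an implanted topological group effect
#'
#' @param type `"densify_module"`: complete all within-module edges of one
#'   module in group 2 and raise their correlation by `delta` (raises
#'   clustering/degree of the module's nodes). `"rewire_hub"`: in group 2,
#'   detach a hub from most of its module and attach it to every other
#'   module (raises its betweenness and participation).
#' @param module Index of the targeted module (for `"densify_module"`, and
#'   the hub's home module for `"rewire_hub"`).
#' @param delta Added correlation on the affected edges (the within-module
#'   correlation difference between groups).
#' @param hub Node index of the hub; default the first node of `module`.
#' @return An `fc_effect` list.
#' @export
effect_spec <- function(type = c("densify_module", "rewire_hub"),
                        module = 1, delta = 0.3, hub = NULL) {
  type <- match.arg(type)
  structure(list(type = type, module = module, delta = delta, hub = hub),
    class = "fc_effect"
  )
}

# Base (group-1) ground truth for a config: adjacency + correlation target.
build_ground_truth <- function(config) {
  n <- config$n_rois
  membership <- rep(seq_along(config$module_sizes), config$module_sizes)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (membership[i] == membership[j]) config$p_within else config$p_between
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  corr <- make_target_corr(adj, matrix(config$r_edge, n, n), config$r_background)
  structure(
    list(
      membership = membership,
      adjacency = list(g1 = adj, g2 = adj),
      corr = list(g1 = corr, g2 = corr),
      altered_nodes = integer(0),
      effect = NULL
    ),
    class = "fc_ground_truth"
  )
}

make_target_corr <- function(adj, r_edge_mat, r_background) {
  corr <- ifelse(adj == 1, r_edge_mat, r_background)
  diag(corr) <- 1
  corr
}

#' Implant a topological effect into a ground truth
#'
#' Alters group 2's generating graph (and its target correlations) as
#' specified, leaving group 1 untouched, and records the altered nodes.
#'
#' @param gt An `fc_ground_truth` (as stored in a [simulate_cohort()]
#'   result, or built internally from a config).
#' @param effect An [effect_spec()]; `NULL` returns `gt` unchanged.
#' @param r_edge Baseline edge correlation assigned to unaffected edges
#'   (matches the config's `r_edge` at simulation time).
#' @return The modified `fc_ground_truth`.
#' @export
implant_effect <- function(gt, effect, r_edge = 0.35) {
  if (is.null(effect)) return(gt)
  stopifnot(inherits(gt, "fc_ground_truth"), inherits(effect, "fc_effect"))
  adj <- gt$adjacency$g1
  n <- ncol(adj)
  membership <- gt$membership
  r_mat <- matrix(r_edge, n, n)
  if (effect$type == "densify_module") {
    nodes <- which(membership == effect$module)
    for (i in nodes) {
      for (j in nodes) {
        if (i < j) {
          adj[i, j] <- adj[j, i] <- 1L
          r_mat[i, j] <- r_mat[j, i] <- r_edge + effect$delta
        }
      }
    }
    altered <- nodes
  } else { # rewire_hub
    hub <- if (is.null(effect$hub)) which(membership == effect$module)[1] else effect$hub
    home <- which(membership == membership[hub] & seq_len(n) != hub)
    keep <- home[seq_len(min(1, length(home)))]
    drop <- setdiff(home, keep)
    adj[hub, drop] <- adj[drop, hub] <- 0L
    for (m in setdiff(unique(membership), membership[hub])) {
      targets <- which(membership == m)[1:min(2, sum(membership == m))]
      adj[hub, targets] <- adj[targets, hub] <- 1L
      r_mat[hub, targets] <- r_mat[targets, hub] <- r_edge + effect$delta
    }
    altered <- hub
  }
  gt$adjacency$g2 <- adj
  gt$corr$g2 <- make_target_corr(adj, r_mat, attr(gt, "r_background") %||% 0.03)
  gt$altered_nodes <- altered
  gt$effect <- effect
  gt
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Eigenvalue-clipping nearest-positive-definite repair, rescaled back to a
# correlation matrix. Returns the matrix plus whether clipping occurred.
nearest_pd_corr <- function(m, floor_ev = 1e-6) {
  ev <- eigen(m, symmetric = TRUE)
  clipped <- any(ev$values < floor_ev)
  if (clipped) {
    vals <- pmax(ev$values, floor_ev)
    m <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    m <- stats::cov2cor(m)
  }
  list(corr = m, clipped = clipped)
}

#' Simulate a two-group cohort of ROI time series with known ground truth
#'
#' Draws each subject's series from a zero-mean multivariate normal whose
#' correlation matrix is the subject's group target (see
#' [simulation_config()]) plus symmetric subject-level jitter, repaired to
#' positive definite by eigenvalue clipping when needed (a message reports
#' how many subjects required repair). Columns are standardized. Ages are
#' drawn to populate all five cohort age bands; group labels are balanced
#' (group 1 = HC, group 2 = ASD).
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (tibble in the exact shape [read_cohort()]
#'   returns) and `ground_truth` (`fc_ground_truth`: per-group generating
#'   adjacency + correlation targets, module membership, altered nodes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_rois
  labels <- sprintf("R%03d", seq_len(n))
  withr::with_seed(config$seed, {
    gt <- build_ground_truth(config)
    attr(gt, "r_background") <- config$r_background
    gt <- implant_effect(gt, config$effect, r_edge = config$r_edge)
    n_total <- 2 * config$n_per_group
    diagnosis <- rep(c("HC", "ASD"), each = config$n_per_group)
    group_corr <- list(HC = gt$corr$g1, ASD = gt$corr$g2)
    age_lo <- c(6, 10, 15, 20, 30)
    age_hi <- c(10, 15, 20, 30, 45)
    band <- ((seq_len(n_total) - 1L) %% 5L) + 1L
    ages <- round(runif(n_total, age_lo[band], age_hi[band]), 1)
    n_repaired <- 0L
    ts_list <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      target <- group_corr[[diagnosis[s]]]
      jit <- matrix(rnorm(n * n, sd = config$jitter_sd), n, n)
      jit <- (jit + t(jit)) / 2
      diag(jit) <- 0
      repaired <- nearest_pd_corr(target + jit)
      if (repaired$clipped) n_repaired <- n_repaired + 1L
      x <- MASS::mvrnorm(config$t_timepoints, mu = rep(0, n),
                         Sigma = repaired$corr)
      x <- scale(x)
      attr(x, "scaled:center") <- NULL
      attr(x, "scaled:scale") <- NULL
      colnames(x) <- labels
      ts_list[[s]] <- x
    }
    if (n_repaired > 0) {
      message(
        "Nearest-PD repair (eigenvalue clipping at 1e-6) applied for ",
        n_repaired, " of ", n_total, " subjects."
      )
    }
    cohort <- tibble::tibble(
      subject_id = sprintf("sub%03d", seq_len(n_total)),
      site = "SYN",
      age = ages,
      age_group = assign_age_group(ages),
      diagnosis = factor(diagnosis, levels = c("ASD", "HC")),
      ts = ts_list
    )
  })
  list(cohort = cohort, ground_truth = gt)
}

#' Write a cohort to disk in the loadable on-disk format
#'
#' Writes `phenotype.csv` plus one `<subject_id>.tsv` per subject (header
#' row of ROI labels, tab-separated), i.e. exactly what [read_cohort()]
#' reads; optionally a `ground_truth.json`.
#'
#' @param cohort Cohort tibble (e.g. `simulate_cohort(config)$cohort`).
#' @param dir Output directory (created if needed).
#' @param ground_truth Optional `fc_ground_truth` to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, ground_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(
    data.frame(
      subject_id = cohort$subject_id, site = cohort$site, age = cohort$age,
      diagnosis = as.character(cohort$diagnosis)
    ),
    file.path(dir, "phenotype.csv"),
    row.names = FALSE
  )
  for (i in seq_len(nrow(cohort))) {
    utils::write.table(
      cohort$ts[[i]],
      file.path(dir, paste0(cohort$subject_id[i], ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  if (!is.null(ground_truth)) {
    jsonlite::write_json(
      list(
        membership = ground_truth$membership,
        adjacency_g1 = ground_truth$adjacency$g1,
        adjacency_g2 = ground_truth$adjacency$g2,
        altered_nodes = ground_truth$altered_nodes,
        effect = if (is.null(ground_truth$effect)) NULL else
          unclass(ground_truth$effect)
      ),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
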