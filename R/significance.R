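# Ranking significance from randomized-network null ensembles.

#' Build a per-gene null ensemble of ranking scores
#'
#' Generates `replicates` randomized copies of the network, runs the full
#' ranking on each, and collects every gene's converged score. A normal is
#' fitted per gene by the sample mean and standard deviation.
#'
#' Replicate r draws its own seed from a deterministic substream of
#' `rng_seed`, so ensembles are reproducible.
#'
#' @param net the observed [gene_network].
#' @param global_net optional full interaction collection (see
#'   [winner_rank()]).
#' @param config a [ranking_config()].
#' @param method randomization scheme, see [randomize_network()].
#' @param replicates number of randomized networks; 1000 by default.
#' @param fraction edge fraction for the add/remove schemes.
#' @param rng_seed seed for the ensemble.
#' @return object of class `winner_null`: list with `scores` (replicates x
#'   genes matrix), `mu`, `sigma` (named numerics), `method`, `replicates`.
#' @export
build_null <- function(net, global_net = NULL, config = ranking_config(),
                       method = "preserve_degree", replicates = 1000,
                       fraction = 0.05, rng_seed = NULL) {
  stopifnot(replicates >= 1)
  local_seed(rng_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  genes <- net$nodes
  scores <- matrix(NA_real_, replicates, length(genes),
                   dimnames = list(NULL, genes))
  for (r in seq_len(replicates)) {
    rnet <- randomize_network(net, method = method, fraction = fraction,
                              rng_seed = sub_seeds[r])
    res <- winner_rank(rnet, global_net, config)
    scores[r, ] <- res$scores[genes]
  }
  mu <- colMeans(scores)
  sigma <- apply(scores, 2, stats::sd)
  structure(list(scores = scores, mu = mu, sigma = sigma,
                 method = method, replicates = replicates),
            class = "winner_null")
}

#' @export
print.winner_null <- function(x, ...) {
  cat(sprintf("<winner_null> %s, %d replicates x %d genes\n",
              x$method, x$replicates, ncol(x$scores)))
  invisible(x)
}

#' Ranking p-value under a fitted normal null
#'
#' Integrates the normal tail on the side of the observed score: the mass
#' below the observation when it falls under the null mean, the mass above
#' it otherwise (exactly 0.5 at the mean). With `double_tail = TRUE` the
#' tail mass is doubled (a conventional two-sided p-value, capped at 1);
#' the default reports the single printed tail, which never exceeds 0.5.
#'
#' A degenerate null (`sigma = 0`) returns 1 when the observation equals
#' the mean and 0 otherwise.
#'
#' @param observed observed converged score(s); vectorized.
#' @param mu,sigma null normal parameters (recycled).
#' @param double_tail double the tail mass?
#' @return numeric p-value(s) in \[0, 1\].
#' @export
ranking_pvalue <- function(observed, mu, sigma, double_tail = FALSE) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  n <- max(length(observed), length(mu), length(sigma))
  observed <- rep_len(observed, n)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  p <- ifelse(observed < mu,
              stats::pnorm(observed, mu, sigma),
              stats::pnorm(observed, mu, sigma, lower.tail = FALSE))
  deg <- sigma == 0
  p[deg] <- ifelse(observed[deg] == mu[deg], 1, 0)
  # at the mean both tails hold half the mass
  p[!deg & observed == mu] <- 0.5
  if (double_tail) p <- pmin(1, 2 * p)
  p
}

#' Attach ranking p-values to a ranking result
#'
#' @param result a `winner_ranking` from [winner_rank()].
#' @param null a `winner_null` from [build_null()] over the same genes.
#' @param double_tail see [ranking_pvalue()].
#' @return the `winner_ranking` with `p_r`, `mu` and `sigma` fields added
#'   (named by gene); `as.data.frame()` then includes them.
#' @export
score_significance <- function(result, null, double_tail = FALSE) {
  genes <- names(result$scores)
  missing <- setdiff(genes, names(null$mu))
  if (length(missing)) {
    stop("null ensemble lacks genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  result$mu <- null$mu[genes]
  result$sigma <- null$sigma[genes]
  result$p_r <- ranking_pvalue(result$scores, result$mu, result$sigma,
                               double_tail = double_tail)
  names(result$p_r) <- genes
  result
}

#' Noise robustness of the ranking
#'
#' Repeatedly spikes the network with a fraction of spurious interactions,
#' re-ranks, and records per gene whether its rank moved by at least
#' `rank_change`. Results are summarized separately for genes called
#' significant (`p_r < alpha`) and not, to check that significant genes'
#' ranks are the more stable ones.
#'
#' @param net the observed [gene_network].
#' @param global_net optional full interaction collection.
#' @param config a [ranking_config()].
#' @param p_values named per-gene ranking p-values (see
#'   [score_significance()]).
#' @param noise_fractions fractions of spurious edges to add, each in
#'   \[0, 1).
#' @param replicates perturbed networks per fraction.
#' @param rank_change rank-shift threshold counted as a change; default 10.
#' @param alpha significance cut for the two gene groups; default 0.05.
#' @param rng_seed seed.
#' @return data.frame with columns `fraction`, `group`
#'   (`"significant"`/`"non_significant"`), `n_genes`, `prob_change`
#'   (empirical probability of a >= `rank_change` rank shift).
#' @export
noise_robustness <- function(net, global_net = NULL,
                             config = ranking_config(), p_values,
                             noise_fractions = c(0.05, 0.1),
                             replicates = 100, rank_change = 10,
                             alpha = 0.05, rng_seed = NULL) {
  stopifnot(all(noise_fractions >= 0), all(noise_fractions < 1))
  local_seed(rng_seed)
  base <- winner_rank(net, global_net, config)
  genes <- names(base$ranks)
  sig <- names(p_values)[p_values < alpha]
  grp <- ifelse(genes %in% sig, "significant", "non_significant")
  out <- list()
  for (f in noise_fractions) {
    changed <- matrix(FALSE, replicates, length(genes),
                      dimnames = list(NULL, genes))
    if (f > 0) {
      sub_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
      for (r in seq_len(replicates)) {
        pert <- perturb_edges(net, f, "add", rng_seed = sub_seeds[r])
        res <- winner_rank(pert, global_net, config)
        changed[r, ] <- abs(res$ranks[genes] - base$ranks[genes]) >=
          rank_change
      }
    }
    for (g in c("significant", "non_significant")) {
      cols <- genes[grp == g]
      out[[length(out) + 1]] <- data.frame(
        fraction = f, group = g, n_genes = length(cols),
        prob_change = if (length(cols)) {
          mean(changed[, cols, drop = FALSE])
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
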