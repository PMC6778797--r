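#' Simulation configuration for the forward meiosis model
#'
#' Defines the generative model for a synthetic testcross experiment:
#' a distribution of exchange (crossover) counts per tetrad, a positional
#' intensity profile over the scoring intervals, optional crossover
#' assurance, an optional non-interfering class II pathway, and the
#' replicate-cross design.
#'
#' The exchange model is one of
#' \describe{
#'   \item{explicit}{`E` gives the exchange-class frequencies E_0..E_N
#'     directly; counts are drawn categorically.}
#'   \item{poisson}{counts are Poisson with mean `lambda` (no
#'     interference).}
#'   \item{counting}{a counting-model interference process: exchanges are
#'     every (m+1)-th event of an underlying Poisson process along the
#'     (profile-warped) chromosome axis, with a stationary random phase,
#'     scaled so the retained events have mean `target_mean`. Larger `m`
#'     means stronger interference; `m = 0` reduces to Poisson.}
#' }
#'
#' @param map a [marker_map()].
#' @param n_crosses number of replicate crosses.
#' @param progeny_per_cross integer, or vector of length `n_crosses`, or a
#'   2-element range `c(lo, hi)` from which per-cross sizes are drawn
#'   uniformly (emulating unequal cross sizes).
#' @param model `"explicit"`, `"poisson"` or `"counting"`.
#' @param E exchange-class frequencies (explicit model).
#' @param lambda Poisson mean (poisson model).
#' @param m interference parameter of the counting model (skipped events
#'   between retained ones).
#' @param target_mean mean exchanges per tetrad (counting model).
#' @param intensity nonnegative weights, one per interval: the relative
#'   probability that an exchange falls in each interval (normalised
#'   internally). Default uniform.
#' @param assurance if `TRUE`, zero-exchange draws are resampled so every
#'   tetrad has at least one (obligate) exchange.
#' @param class2_rate mean number of additional non-interfering class II
#'   exchanges per tetrad (Poisson, placed uniformly over intervals
#'   regardless of `intensity`).
#' @param genotype_label label attached to the simulated collection.
#' @param seed integer seed; the seed fully determines the output.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(map, n_crosses = 13L, progeny_per_cross = 150L,
                       model = c("explicit", "poisson", "counting"),
                       E = NULL, lambda = NULL, m = 4L, target_mean = NULL,
                       intensity = NULL, assurance = FALSE,
                       class2_rate = 0, genotype_label = "sim",
                       seed = 1L) {
  stopifnot(inherits(map, "marker_map"))
  model <- match.arg(model)
  n_crosses <- as.integer(n_crosses)
  if (is.na(n_crosses) || n_crosses < 1L)
    stop("n_crosses must be a positive integer", call. = FALSE)
  if (model == "explicit") {
    if (is.null(E) || any(!is.finite(E)) || any(E < 0) || sum(E) <= 0)
      stop("explicit model needs a nonnegative E vector", call. = FALSE)
    E <- E / sum(E)
  } else if (model == "poisson") {
    if (is.null(lambda) || !is.finite(lambda) || lambda < 0)
      stop("poisson model needs lambda >= 0", call. = FALSE)
  } else {
    m <- as.integer(m)
    if (is.na(m) || m < 0L) stop("counting model needs m >= 0", call. = FALSE)
    if (is.null(target_mean) || !is.finite(target_mean) || target_mean <= 0)
      stop("counting model needs target_mean > 0", call. = FALSE)
  }
  if (is.null(intensity)) intensity <- rep(1, n_intervals(map))
  if (length(intensity) != n_intervals(map))
    stop("intensity must have one weight per interval", call. = FALSE)
  if (any(!is.finite(intensity)) || any(intensity < 0) || sum(intensity) <= 0)
    stop("intensity weights must be nonnegative, not all zero", call. = FALSE)
  if (!is.finite(class2_rate) || class2_rate < 0)
    stop("class2_rate must be >= 0", call. = FALSE)
  seed <- suppressWarnings(as.integer(seed))
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  structure(
    list(map = map, n_crosses = n_crosses,
         progeny_per_cross = progeny_per_cross, model = model, E = E,
         lambda = lambda, m = m, target_mean = target_mean,
         intensity = intensity / sum(intensity),
         assurance = isTRUE(assurance), class2_rate = class2_rate,
         genotype_label = genotype_label, seed = seed),
    class = "sim_config"
  )
}

#' Draw exchange counts per tetrad
#'
#' @param cfg a [sim_config()].
#' @param n number of tetrads.
#' @return integer vector of exchange counts (class I process only; class
#'   II exchanges are added separately). Assurance resamples zeros, i.e.
#'   draws from the count distribution conditioned on >= 1.
#' @export
draw_exchange_count <- function(cfg, n) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- switch(cfg$model,
    explicit = {
      E <- cfg$E
      if (cfg$assurance) {
        if (sum(E[-1L]) <= 0)
          stop("assurance impossible: all mass on zero exchanges",
               call. = FALSE)
        E <- c(0, E[-1L] / sum(E[-1L]))
      }
      sample(seq_along(E) - 1L, n, replace = TRUE, prob = E)
    },
    poisson = {
      if (cfg$assurance) {
        # zero-truncated Poisson via inverse CDF on U(P(0), 1)
        u <- stats::runif(n, stats::ppois(0, cfg$lambda), 1)
        stats::qpois(u, cfg$lambda)
      } else stats::rpois(n, cfg$lambda)
    },
    counting = {
      x <- counting_draw(cfg, n)
      if (cfg$assurance) {
        while (any(x$count == 0L)) {
          z <- which(x$count == 0L)
          redo <- counting_draw(cfg, length(z))
          x$count[z] <- redo$count
          x$pos[z] <- redo$pos
        }
      }
      attr(x$count, "positions") <- x$pos
      x$count
    })
  as.integer(counts)
}

# Counting-model draw: underlying Poisson process of rate (m+1)*mu on
# [0, 1]; every (m+1)-th event retained, with a uniform random phase so
# the retained process is stationary. Returns counts and retained
# positions (class I exchange positions on the warped axis).
counting_draw <- function(cfg, n) {
  m1 <- cfg$m + 1L
  rate <- m1 * cfg$target_mean
  n_events <- stats::rpois(n, rate)
  phase <- sample.int(m1, n, replace = TRUE)  # which residue is retained
  pos <- vector("list", n)
  count <- integer(n)
  for (i in seq_len(n)) {
    if (n_events[i] == 0L) next
    u <- sort(stats::runif(n_events[i]))
    keep <- seq_len(n_events[i]) %% m1 == phase[i] %% m1
    pos[[i]] <- u[keep]
    count[i] <- sum(keep)
  }
  list(count = count, pos = pos)
}

#' Place exchanges into intervals
#'
#' For the explicit and Poisson models each exchange is assigned
#' independently to interval i with probability proportional to the
#' intensity weight. For the counting model the underlying process runs
#' along a profile-warped axis: the unit axis is cut at the cumulative
#' intensity weights and each retained position maps to its interval, so
#' interference acts in genetic (intensity-weighted) distance.
#'
#' @param cfg a [sim_config()].
#' @param counts integer vector of exchange counts per tetrad (with the
#'   counting model, as returned by [draw_exchange_count()], carrying
#'   position attributes).
#' @return list of integer vectors of interval indices, one per tetrad.
#' @export
place_exchanges <- function(cfg, counts) {
  stopifnot(inherits(cfg, "sim_config"))
  w <- cfg$intensity
  k <- length(w)
  pos_attr <- attr(counts, "positions")
  if (cfg$model == "counting" && !is.null(pos_attr)) {
    breaks <- c(0, cumsum(w))
    return(lapply(pos_attr, function(u) {
      if (is.null(u) || length(u) == 0L) integer(0)
      else as.integer(findInterval(u, breaks, rightmost.closed = TRUE))
    }))
  }
  total <- sum(counts)
  iv <- if (total > 0)
    sample.int(k, total, replace = TRUE, prob = w) else integer(0)
  split_by_tetrad(iv, counts)
}

# Split a flat vector into per-tetrad pieces of given lengths.
split_by_tetrad <- function(x, lens) {
  idx <- rep.int(seq_along(lens), lens)
  out <- vector("list", length(lens))
  nonzero <- lens > 0L
  out[nonzero] <- unname(split(x, idx))
  out[!nonzero] <- list(integer(0))
  out
}

#' Sample the recovered chromatid of a tetrad
#'
#' Under no chromatid interference each exchange involves 2 of the 4
#' chromatids chosen independently, so the single recovered chromatid
#' carries each exchange independently with probability 1/2. This is the
#' assumption that makes the Weinstein inversion exact.
#'
#' @param positions integer vector of exchange interval indices for one
#'   tetrad.
#' @return integer vector: the subset of `positions` carried by the
#'   recovered chromatid.
#' @export
sample_chromatid <- function(positions) {
  if (length(positions) == 0L) return(integer(0))
  positions[stats::runif(length(positions)) < 0.5]
}

#' Emit a progeny genotype from chromatid crossover positions
#'
#' Starting in the parental phase "M" at the first marker, the phase
#' flips after every interval carrying an odd number of chromatid
#' crossovers; an even number in one interval cancels (unobservable
#' double). Hidden doubles are counted for the truth log.
#'
#' @param crossover_intervals integer vector of interval indices hit on
#'   the chromatid (repeats allowed).
#' @param map a [marker_map()].
#' @return character state vector over the markers, with attribute
#'   `hidden_dco` = number of intervals carrying >= 2 hits.
#' @export
emit_genotype <- function(crossover_intervals, map) {
  stopifnot(inherits(map, "marker_map"))
  k <- n_markers(map)
  hits <- tabulate(crossover_intervals, nbins = k - 1L)
  phase <- cumsum(c(0L, hits)) %% 2L
  geno <- c("M", "W")[phase + 1L]
  attr(geno, "hidden_dco") <- sum(hits >= 2L)
  geno
}

#' Simulate a replicate-cross testcross experiment
#'
#' Runs the forward model: per tetrad, draw an exchange count, place the
#' exchanges along the intervals, add any class II exchanges, sample the
#' recovered chromatid, and emit the progeny genotype. One tetrad is
#' sampled per progeny. Fully deterministic given the seed; each cross
#' uses a substream derived from (seed, cross index).
#'
#' @param cfg a [sim_config()].
#' @return list with `collection` (a [cross_collection()]) and `truth`,
#'   a data frame logging every tetrad: `cross_id`, `progeny_id`,
#'   `n_exchanges` (class I + class II), `n_class2`, `positions`
#'   (comma-joined interval indices), `chromatid_hits`, `n_observed`
#'   (switch count on the emitted genotype), `hidden_dco`.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- cross_sizes(cfg)
  k <- n_markers(cfg$map)
  genos <- vector("list", cfg$n_crosses)
  truths <- vector("list", cfg$n_crosses)
  for (cx in seq_len(cfg$n_crosses)) {
    set.seed(substream_seed(cfg$seed, cx))
    n <- sizes[cx]
    counts <- draw_exchange_count(cfg, n)
    placed <- place_exchanges(cfg, counts)
    if (cfg$class2_rate > 0) {
      extra <- stats::rpois(n, cfg$class2_rate)
      extra_pos <- split_by_tetrad(
        sample.int(k - 1L, sum(extra), replace = TRUE), extra)
      placed <- mapply(c, placed, extra_pos, SIMPLIFY = FALSE)
    } else extra <- integer(n)
    carried <- lapply(placed, sample_chromatid)
    gm <- matrix("M", n, k)
    hidden <- integer(n)
    nobs <- integer(n)
    for (i in seq_len(n)) {
      g <- emit_genotype(carried[[i]], cfg$map)
      gm[i, ] <- g
      hidden[i] <- attr(g, "hidden_dco")
      nobs[i] <- sum(g[-k] != g[-1L])
    }
    cid <- sprintf("cross%02d", cx)
    pid <- sprintf("%s_p%04d", cid, seq_len(n))
    genos[[cx]] <- list(g = gm, cid = cid, pid = pid)
    truths[[cx]] <- data.frame(
      cross_id = cid, progeny_id = pid,
      n_exchanges = lengths(placed), n_class2 = extra,
      positions = vapply(placed, paste, "", collapse = ","),
      chromatid_hits = vapply(carried, paste, "", collapse = ","),
      n_observed = nobs, hidden_dco = hidden,
      stringsAsFactors = FALSE)
  }
  geno <- do.call(rbind, lapply(genos, `[[`, "g"))
  coll <- cross_collection(
    geno,
    cross_id = unlist(lapply(genos, function(x) rep(x$cid, nrow(x$g)))),
    progeny_id = unlist(lapply(genos, `[[`, "pid")),
    map = cfg$map, genotype_label = cfg$genotype_label)
  list(collection = coll, truth = do.call(rbind, truths))
}

# Deterministic per-cross substream seed below 2^31.
substream_seed <- function(seed, cross_index) {
  (as.numeric(seed) * 48271 + cross_index * 16807) %% 2147483647
}

cross_sizes <- function(cfg) {
  pp <- cfg$progeny_per_cross
  if (length(pp) == cfg$n_crosses) return(as.integer(pp))
  if (length(pp) == 1L) return(rep(as.integer(pp), cfg$n_crosses))
  if (length(pp) == 2L) {
    set.seed(substream_seed(cfg$seed, 0L))
    return(sample(as.integer(pp[1L]):as.integer(pp[2L]), cfg$n_crosses,
                  replace = TRUE))
  }
  stop("progeny_per_cross must be scalar, a range, or per-cross",
       call. = FALSE)
}
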