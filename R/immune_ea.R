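# The modified immune evolutionary algorithm (MIEA): a real-coded genetic
# algorithm over cluster-center chromosomes with adaptive vaccine extraction,
# vaccination, immune selection, and elitism, minimizing the fuzzy c-means
# objective through the fitness transform f = 1/(J+1).

#' Encode cluster centers as a flat chromosome / decode one back
#'
#' A chromosome concatenates the c centers row-major: genes
#' \code{(i-1)*p + 1 .. i*p} hold center \code{i}. The encoding length
#' \code{l = c * p} is independent of the sample count, which is what makes
#' center encoding tractable compared with encoding the partition itself
#' (search space c^n).
#'
#' @param V c x p matrix of cluster centers.
#' @return numeric vector of length \code{c * p}.
#' @export
encode_chromosome <- function(V) {
  as.numeric(t(as.matrix(V)))
}

#' @rdname encode_chromosome
#' @param a numeric chromosome of length \code{c * p}.
#' @param c number of clusters.
#' @param p feature dimensionality.
#' @export
decode_chromosome <- function(a, c, p) {
  if (length(a) != c * p)
    stop("chromosome length ", length(a), " != c * p = ", c * p)
  matrix(a, nrow = c, ncol = p, byrow = TRUE)
}

#' MIEA configuration
#'
#' Collects the evolutionary parameters. Defaults follow the usual operating
#' ranges for real-coded immune genetic algorithms: crossover probability in
#' [0.75, 0.95] (default 0.95), per-gene mutation probability in
#' [1e-3, 1e-2] (default 5e-3), vaccination probability 0.3.
#'
#' @param c number of clusters (required).
#' @param m fuzzifier, > 1.
#' @param p_n population size, >= 2.
#' @param p_c crossover probability.
#' @param p_m per-gene mutation probability.
#' @param p_v per-individual vaccination probability.
#' @param p_u probability of re-extracting the vaccine from the current elite
#'   in a generation where the elite did not improve.
#' @param tau stop tolerance: the run stops once the elite objective changes
#'   by less than \code{tau} for \code{patience} consecutive generations.
#' @param patience consecutive near-stationary generations required to stop.
#' @param max_gens generation cap.
#' @param selection \code{"roulette"} (fitness-proportionate) or
#'   \code{"rank"} (linear rank weights).
#' @param vaccine_fraction share of the elite's genes donated to the vaccine,
#'   in (0, 1].
#' @param crossover \code{"one_point"}, \code{"two_point"} or
#'   \code{"uniform"}.
#' @param mutation \code{"reset"} (uniform re-randomization within feature
#'   bounds) or \code{"segment_reversal"} (reverse a random gene slice).
#' @param seed integer seed driving all randomness of [run_miea()].
#' @return An object of class \code{miea_config}.
#' @export
miea_config <- function(c, m = 2, p_n = 30L, p_c = 0.95, p_m = 5e-3,
                        p_v = 0.3, p_u = 0.5, tau = 1e-6, patience = 10L,
                        max_gens = 100L,
                        selection = c("roulette", "rank"),
                        vaccine_fraction = 0.25,
                        crossover = c("one_point", "two_point", "uniform"),
                        mutation = c("reset", "segment_reversal"),
                        seed = NULL) {
  selection <- match.arg(selection)
  crossover <- match.arg(crossover)
  mutation <- match.arg(mutation)
  stopifnot(c >= 1, m > 1, p_n >= 2,
            p_c >= 0, p_c <= 1, p_m >= 0, p_m <= 1,
            p_v >= 0, p_v <= 1, p_u >= 0, p_u <= 1,
            tau > 0, patience >= 1, max_gens >= 1,
            vaccine_fraction > 0, vaccine_fraction <= 1)
  structure(list(c = as.integer(c), m = m, p_n = as.integer(p_n),
                 p_c = p_c, p_m = p_m, p_v = p_v, p_u = p_u, tau = tau,
                 patience = as.integer(patience),
                 max_gens = as.integer(max_gens), selection = selection,
                 vaccine_fraction = vaccine_fraction, crossover = crossover,
                 mutation = mutation, seed = seed),
            class = "miea_config")
}

#' Initialize a random population of center chromosomes
#'
#' Each gene is drawn uniformly within its feature's observed range, so every
#' initial candidate center lies inside the data's bounding box.
#'
#' @param cfg a [miea_config()].
#' @param X a [labeled_dataset()] or numeric matrix.
#' @return \code{p_n} x \code{(c*p)} matrix, one chromosome per row, with
#'   attributes \code{lo}/\code{hi}: the per-gene bounds.
#' @export
init_population <- function(cfg, X) {
  X <- as_feature_matrix(X)
  lo <- rep(apply(X, 2L, min), times = cfg$c)
  hi <- rep(apply(X, 2L, max), times = cfg$c)
  l <- cfg$c * ncol(X)
  pop <- matrix(stats::runif(cfg$p_n * l, rep(lo, each = cfg$p_n),
                             rep(hi, each = cfg$p_n)), cfg$p_n, l)
  attr(pop, "lo") <- lo
  attr(pop, "hi") <- hi
  pop
}

#' Select chromosomes by fitness
#'
#' Roulette-wheel selection samples with replacement with probability
#' proportional to fitness; rank selection uses linear rank weights
#' (probability proportional to the fitness rank), which is invariant to any
#' monotone rescaling of fitness.
#'
#' @param population chromosome matrix, one row per individual.
#' @param fitnesses positive fitness per individual.
#' @param method \code{"roulette"} or \code{"rank"}.
#' @param n_out number of individuals to draw.
#' @return matrix of \code{n_out} selected chromosomes (rows).
#' @export
select_parents <- function(population, fitnesses,
                           method = c("roulette", "rank"), n_out) {
  method <- match.arg(method)
  if (nrow(population) == 0L) stop("empty population")
  stopifnot(length(fitnesses) == nrow(population), n_out >= 1)
  prob <- switch(method,
    roulette = fitnesses,
    rank = rank(fitnesses, ties.method = "average"))
  idx <- sample.int(nrow(population), n_out, replace = TRUE, prob = prob)
  population[idx, , drop = FALSE]
}

#' Crossover two parent chromosomes
#'
#' With probability \code{p_c} the parents recombine; otherwise they are
#' copied unchanged. One-point crossover swaps the tails after a uniform cut
#' in \code{1..l-1}; two-point swaps the segment between two cuts; uniform
#' swaps each gene independently with probability 1/2. Every child gene comes
#' verbatim from one of the parents, so feature bounds are preserved.
#'
#' @param parent1,parent2 chromosomes of equal length.
#' @param p_c crossover probability.
#' @param method crossover variant.
#' @return list of two child chromosomes.
#' @export
crossover_chromosomes <- function(parent1, parent2, p_c = 0.95,
                                  method = c("one_point", "two_point",
                                             "uniform")) {
  method <- match.arg(method)
  l <- length(parent1)
  if (length(parent2) != l) stop("parent chromosomes differ in length")
  if (l < 2L || stats::runif(1) >= p_c)
    return(list(parent1, parent2))
  swap <- switch(method,
    one_point = {
      cut <- sample.int(l - 1L, 1L)
      seq_len(l) > cut
    },
    two_point = {
      cuts <- sort(sample.int(l - 1L, 2L, replace = TRUE))
      seq_len(l) > cuts[1L] & seq_len(l) <= cuts[2L] + 1L
    },
    uniform = stats::runif(l) < 0.5)
  child1 <- parent1; child2 <- parent2
  child1[swap] <- parent2[swap]
  child2[swap] <- parent1[swap]
  list(child1, child2)
}

#' Mutate a chromosome
#'
#' \code{"reset"} mutation re-randomizes each gene independently with
#' probability \code{p_m}, drawing uniformly within that gene's feature
#' bounds. \code{"segment_reversal"} instead, with probability \code{p_m}
#' per chromosome, reverses a randomly chosen gene slice (an inversion
#' operator carried over from binary-coded genetic algorithms).
#'
#' @param a chromosome.
#' @param p_m mutation probability (per gene for \code{"reset"}, per
#'   chromosome for \code{"segment_reversal"}).
#' @param lo,hi per-gene lower and upper bounds.
#' @param method mutation variant.
#' @return mutated chromosome, always within \code{[lo, hi]}.
#' @export
mutate_chromosome <- function(a, p_m, lo, hi,
                              method = c("reset", "segment_reversal")) {
  method <- match.arg(method)
  stopifnot(p_m >= 0, p_m <= 1)
  l <- length(a)
  if (method == "reset") {
    hit <- stats::runif(l) < p_m
    if (any(hit))
      a[hit] <- stats::runif(sum(hit), lo[hit], hi[hit])
  } else if (stats::runif(1) < p_m && l >= 2L) {
    ends <- sort(sample.int(l, 2L))
    a[ends[1L]:ends[2L]] <- rev(a[ends[1L]:ends[2L]])
  }
  a
}

#' Extract a vaccine from the elite chromosome
#'
#' Adaptive vaccine extraction: rather than relying on problem-specific prior
#' knowledge, the vaccine harvests gene fragments from the current best
#' individual. \code{ceiling(vaccine_fraction * l)} distinct positions are
#' chosen uniformly and carry the elite's values.
#'
#' @param elite the donor chromosome.
#' @param elite_f the donor's fitness (recorded for provenance).
#' @param vaccine_fraction share of positions donated, in (0, 1].
#' @return An object of class \code{miea_vaccine}: list with
#'   \code{positions} (1-based gene indices), \code{values},
#'   \code{source_fitness}.
#' @export
extract_vaccine <- function(elite, elite_f, vaccine_fraction = 0.25) {
  stopifnot(vaccine_fraction > 0, vaccine_fraction <= 1)
  l <- length(elite)
  k <- ceiling(vaccine_fraction * l)
  pos <- sort(sample.int(l, k))
  structure(list(positions = pos, values = elite[pos],
                 source_fitness = elite_f),
            class = "miea_vaccine")
}

#' Vaccinate a chromosome
#'
#' With probability \code{p_v} the vaccine's gene values overwrite the
#' chromosome at the vaccine's positions; otherwise the chromosome is
#' returned unchanged. Vaccination transmits good partial solutions; immune
#' selection ([immune_select()]) then decides whether to keep the result.
#'
#' @param a chromosome.
#' @param vaccine a \code{miea_vaccine} from [extract_vaccine()].
#' @param p_v vaccination probability.
#' @return possibly-vaccinated chromosome.
#' @export
vaccinate <- function(a, vaccine, p_v = 0.3) {
  stopifnot(inherits(vaccine, "miea_vaccine"))
  if (any(vaccine$positions < 1L) || any(vaccine$positions > length(a)))
    stop("vaccine positions out of range for this chromosome")
  if (stats::runif(1) < p_v)
    a[vaccine$positions] <- vaccine$values
  a
}

#' Immune selection
#'
#' Greedy anti-degradation acceptance: the vaccinated individual replaces the
#' original if and only if its fitness is not worse. This is what prevents
#' vaccination from ever degrading an individual.
#'
#' @param original,vaccinated two chromosomes.
#' @param f_original,f_vaccinated their fitnesses.
#' @return list with \code{chromosome} and \code{f}: the accepted individual
#'   (ties accept the vaccinated one).
#' @export
immune_select <- function(original, vaccinated, f_original, f_vaccinated) {
  if (f_vaccinated >= f_original)
    list(chromosome = vaccinated, f = f_vaccinated)
  else
    list(chromosome = original, f = f_original)
}

#' Cluster a dataset with the modified immune evolutionary algorithm
#'
#' Runs the full MIEA loop: evaluate every chromosome through the fuzzy
#' c-means pipeline (decode centers, squared distances, membership update,
#' objective, fitness), track the elite and extract a vaccine from it,
#' produce offspring by fitness-proportionate (or rank) selection, crossover
#' and mutation, vaccinate offspring and apply immune selection, and carry
#' the elite unmodified into the next generation. The elite objective is
#' non-increasing by construction. The run stops when the elite objective has
#' changed by less than \code{tau} for \code{patience} consecutive
#' generations, or at \code{max_gens}.
#'
#' @param X a [labeled_dataset()] or numeric matrix.
#' @param cfg a [miea_config()]; \code{cfg$seed} makes the run fully
#'   reproducible.
#' @param scale min-max scale features internally before clustering (default
#'   \code{TRUE})? Prototypes in the result are always reported in the
#'   original data units; \code{J} and \code{U} refer to the space the
#'   optimization ran in.
#' @param refine polish the decoded elite with [fcm_refine()] after the
#'   evolutionary loop (default \code{TRUE})? The evolutionary search is a
#'   global, coarse optimizer: crossover and vaccination only recombine and
#'   copy existing gene values, and uniform reset mutation rarely lands near
#'   an optimum, so the decoded elite identifies the right basin but not its
#'   floor. Alternating-optimization descent from the elite reaches the
#'   basin's local minimum; because it starts from the evolved elite, the
#'   division of labor is global search by MIEA, local convergence by
#'   descent.
#' @return An object of class \code{miea_result}: list with
#'   \code{prototypes} (c x p, data units), \code{U} (c x n),
#'   \code{hard_labels} (0-based, argmax memberships, ties to the lowest
#'   index), \code{J}, \code{f_best}, \code{J_history} (elite J per
#'   generation), \code{best_chromosome} (in optimization space),
#'   \code{generations_run}, \code{vaccinations} (accepted vaccinations per
#'   generation), \code{seed}, \code{config}.
#' @examples
#' ds <- generate_mixture(mixture_spec(rbind(c(0, 0), c(5, 5)), spreads = 0.2),
#'                        n = 40, seed = 1)
#' res <- run_miea(ds, miea_config(c = 2, max_gens = 25, seed = 1))
#' res$prototypes
#' @export
run_miea <- function(X, cfg, scale = TRUE, refine = TRUE) {
  stopifnot(inherits(cfg, "miea_config"))
  Xm <- as_feature_matrix(X)
  n <- nrow(Xm)
  if (n < 1L) stop("empty dataset")
  if (cfg$c > n - 1L && n > 1L)
    stop("cluster count c must satisfy 1 <= c <= n - 1")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  scaling <- NULL
  if (scale) {
    sc <- min_max_scale(labeled_dataset(Xm))
    Xm <- sc$dataset$features
    scaling <- sc[c("mins", "maxs")]
  }
  p <- ncol(Xm)
  l <- cfg$c * p

  pop <- init_population(cfg, Xm)
  lo <- attr(pop, "lo"); hi <- attr(pop, "hi")
  eval_pop <- function(P)
    vapply(seq_len(nrow(P)),
           function(i) evaluate_chromosome(P[i, ], Xm, cfg$c, cfg$m)$J,
           numeric(1))

  J_pop <- eval_pop(pop)
  f_pop <- fcm_fitness(J_pop)
  best <- which.min(J_pop)
  elite <- pop[best, ]
  elite_J <- J_pop[best]
  vaccine <- extract_vaccine(elite, fcm_fitness(elite_J),
                             cfg$vaccine_fraction)

  J_history <- numeric(0)
  vaccinations <- integer(0)
  stagnant <- 0L
  gens <- 0L

  for (gen in seq_len(cfg$max_gens)) {
    gens <- gen
    prev_elite_J <- elite_J

    # --- selection, crossover, mutation -> offspring -----------------------
    parents <- select_parents(pop, f_pop, cfg$selection, cfg$p_n)
    offspring <- matrix(0, cfg$p_n, l)
    i <- 1L
    while (i <= cfg$p_n) {
      j <- if (i < cfg$p_n) i + 1L else 1L
      kids <- crossover_chromosomes(parents[i, ], parents[j, ], cfg$p_c,
                                    cfg$crossover)
      offspring[i, ] <- kids[[1L]]
      if (i < cfg$p_n) offspring[i + 1L, ] <- kids[[2L]]
      i <- i + 2L
    }
    for (k in seq_len(cfg$p_n))
      offspring[k, ] <- mutate_chromosome(offspring[k, ], cfg$p_m, lo, hi,
                                          cfg$mutation)
    J_off <- eval_pop(offspring)
    f_off <- fcm_fitness(J_off)

    # --- vaccination + immune selection ------------------------------------
    accepted <- 0L
    for (k in seq_len(cfg$p_n)) {
      vacc <- vaccinate(offspring[k, ], vaccine, cfg$p_v)
      if (!identical(vacc, offspring[k, ])) {
        f_vacc <- evaluate_chromosome(vacc, Xm, cfg$c, cfg$m)$f
        keep <- immune_select(offspring[k, ], vacc, f_off[k], f_vacc)
        if (keep$f != f_off[k] || !identical(keep$chromosome, offspring[k, ])) {
          offspring[k, ] <- keep$chromosome
          J_off[k] <- 1 / keep$f - 1
          f_off[k] <- keep$f
          accepted <- accepted + 1L
        }
      }
    }

    # --- elitism ------------------------------------------------------------
    worst <- which.max(J_off)
    offspring[worst, ] <- elite
    J_off[worst] <- elite_J
    f_off[worst] <- fcm_fitness(elite_J)
    pop <- offspring
    J_pop <- J_off
    f_pop <- f_off

    best <- which.min(J_pop)
    improved <- J_pop[best] < elite_J
    if (improved) {
      elite <- pop[best, ]
      elite_J <- J_pop[best]
      vaccine <- extract_vaccine(elite, fcm_fitness(elite_J),
                                 cfg$vaccine_fraction)
    } else if (stats::runif(1) < cfg$p_u) {
      # refresh the vaccine's positions from the unchanged elite
      vaccine <- extract_vaccine(elite, fcm_fitness(elite_J),
                                 cfg$vaccine_fraction)
    }

    J_history <- c(J_history, elite_J)
    vaccinations <- c(vaccinations, accepted)

    stagnant <- if (abs(prev_elite_J - elite_J) < cfg$tau) stagnant + 1L
                else 0L
    if (stagnant >= cfg$patience) break
  }

  if (refine) {
    # polish to numerical convergence: cfg$tau governs the evolutionary
    # stop rule, not the precision of the finishing descent
    fit <- fcm_refine(Xm, decode_chromosome(elite, cfg$c, p), m = cfg$m,
                      max_iter = 500L, tol = min(cfg$tau, 1e-10))
    elite <- encode_chromosome(fit$V)
  }
  final <- evaluate_chromosome(elite, Xm, cfg$c, cfg$m)
  V <- final$V
  if (!is.null(scaling))
    V <- unscale_prototypes(V, scaling$mins, scaling$maxs)
  hard <- apply(final$U, 2L, which.max) - 1L

  structure(
    list(prototypes = V, U = final$U, hard_labels = as.integer(hard),
         J = final$J, f_best = final$f, J_history = J_history,
         best_chromosome = elite, generations_run = gens,
         vaccinations = vaccinations, seed = cfg$seed, config = cfg,
         scaling = scaling),
    class = "miea_result")
}

#' @export
print.miea_result <- function(x, ...) {
  cat(sprintf(paste0("MIEA clustering: c = %d clusters, J = %.6g, ",
                     "f = %.4f, %d generations\n"),
              x$config$c, x$J, x$f_best, x$generations_run))
  cat("prototypes (data units):\n")
  print(round(x$prototypes, 4))
  invisible(x)
}
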