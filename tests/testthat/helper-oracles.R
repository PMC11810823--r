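# Independent oracles and small fixtures shared across tests.

# Recursive coefficient-of-kinship oracle (memoized); additive relationship
# is twice the kinship. Independent of the tabular method in build_A().
kinship_oracle <- function(pedigree) {
  ids <- as.character(pedigree$id)
  s <- match(as.character(pedigree$sire), ids)
  d <- match(as.character(pedigree$dam), ids)
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(s[i], d[i]))
    } else if (i > j) {
      0.5 * (phi(s[i], j) + phi(d[i], j))
    } else {
      0.5 * (phi(s[j], i) + phi(d[j], i))
    }
    memo[[key]] <- val
    val
  }
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) K[i, j] <- K[j, i] <- phi(i, j)
  K
}

# Random multi-generation pedigree with known and unknown parents.
random_pedigree <- function(n_founders = 10, n_offspring = 40, seed = 1,
                            p_unknown_dam = 0.3) {
  set.seed(seed)
  ids <- sprintf("P%03d", seq_len(n_founders + n_offspring))
  sire <- dam <- rep(NA_character_, n_founders + n_offspring)
  for (i in (n_founders + 1):(n_founders + n_offspring)) {
    sire[i] <- sample(ids[seq_len(i - 1)], 1)
    if (runif(1) > p_unknown_dam) {
      dam[i] <- sample(setdiff(ids[seq_len(i - 1)], sire[i]), 1)
    }
  }
  data.frame(id = ids, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# Balanced one-way sire family design with unrelated sires.
balanced_sire_data <- function(s = 30, k = 10, sigma2_S = 0.2, sigma2_e = 1,
                               seed = 1) {
  set.seed(seed)
  sires <- sprintf("S%03d", seq_len(s))
  eff <- rnorm(s, 0, sqrt(sigma2_S))
  dat <- data.frame(animal_id = sprintf("A%04d", seq_len(s * k)),
                    cage_id = rep(sprintf("c%03d", seq_len(s)), each = k),
                    sire_id = rep(sires, each = k),
                    stringsAsFactors = FALSE)
  dat$y <- 5 + eff[match(dat$sire_id, sires)] +
    rnorm(s * k, 0, sqrt(sigma2_e))
  list(pedigree = data.frame(id = sires, sire = NA, dam = NA),
       data = dat, true_effects = eff)
}

# small default-structure simulation reused by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_rt_data(sim_config(n_sires = 60, seed = 101),
                                 keep_liability = TRUE)
    }
    cache
  }
})
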