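# Independent oracles and random-case generators shared across tests.

# Brute-force equilibrium oracle: plain midpoint bisection on the free
# base-unit concentration, written independently of the package solver
# (which uses bisection + analytic-derivative Newton polish).
oracle_equilibrium <- function(scheme, c_total) {
  b <- scheme$base_order
  orders <- scheme$steps$order
  kds <- scheme$steps$kd
  incr <- c(orders[1] / b, diff(orders) / b)
  total_protomer <- function(x) {
    tot <- b * x
    prev <- 1
    for (j in seq_along(kds)) {
      prev <- prev * x^incr[j] / kds[j]
      tot <- tot + orders[j] * prev
    }
    tot
  }
  lo <- 0; hi <- c_total / b
  for (i in 1:300) {
    mid <- (lo + hi) / 2
    if (total_protomer(mid) > c_total) hi <- mid else lo <- mid
  }
  x <- (lo + hi) / 2
  conc <- numeric(length(orders) + 1)
  conc[1] <- x
  prev <- 1
  for (j in seq_along(kds)) {
    prev <- prev * x^incr[j] / kds[j]
    conc[j + 1] <- prev
  }
  conc
}

# random valid assembly scheme
random_scheme <- function() {
  base <- sample(c("monomer", "obligate_dimer"), 1)
  b <- if (base == "monomer") 1L else 2L
  n_steps <- sample(1:3, 1)
  orders <- b * cumsum(1 + sample(0:2, n_steps, replace = TRUE)) + b
  kds <- 10^stats::runif(n_steps, -2, 2)
  build_scheme("random", protomer_mass = stats::runif(1, 5, 100),
               tag_mass = sample(c(0, stats::runif(1, 5, 20)), 1),
               base_unit = base,
               steps = Map(c, orders, kds))
}

# canonical melting parameter sets
melt_pars_1tr <- function(tm = 37, dh = 200) {
  list(bf = c(-30000, 30), bu = c(-5000, -10), tm = tm, dh = dh)
}
melt_pars_2tr <- function(tm = c(50, 70), dh = c(250, 250),
                          phi = c(0.5, 0.5)) {
  list(bf = c(-30000, 30), bu = c(-5000, -10), tm = tm, dh = dh, phi = phi)
}

# parse a key = value report file into a named list of numerics/strings
read_keyvalue_report <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
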