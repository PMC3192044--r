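# shared fixtures and oracles, built in code

# central finite-difference slope oracle
fd_slope <- function(fun, age, h = 1e-6) {
  (fun(age + h) - fun(age - h)) / (2 * h)
}

# published pes-length parameter sets used as simulation truths
tbl_logistic_pouch <- function() logistic_params(A = 16.06, K = 93.92,
                                                 L0 = 1.11, r = 0.96)
tbl_brody_male_pp <- function() brody_params(B = 154.91, C = 0.567, k = 0.077)
tbl_sj2p_male <- function() sj2p_free_params(C = 0.57, K = 95.21, L0 = 1.22,
                                             k = 0.078, j = 7.85, r = 0.78)
tbl_sj2p_female <- function() sj2p_free_params(C = 0.22, K = 111.42, L0 = 4.34,
                                               k = 0.024, j = 11.56, r = 0.94)

# random valid parameter draws for property tests (assumes caller seeded)
random_curve_params <- function(family) {
  switch(family,
    logistic = {
      K <- runif(1, 20, 200)
      logistic_params(A = runif(1, -20, 30), K = K,
                      L0 = runif(1, 0.01, 0.5) * K, r = runif(1, 0.1, 2))
    },
    brody = brody_params(B = runif(1, 50, 300), C = runif(1, 0.05, 0.95),
                         k = runif(1, 0.05, 1)),
    brody_offset = brody_offset_params(a = runif(1, -5, 30),
                                       b = runif(1, 20, 200),
                                       k = runif(1, 0.05, 1)),
    von_bertalanffy = {
      b <- runif(1, 0.05, 1)
      asy <- runif(1, 50, 300)
      von_bertalanffy_params(L0 = runif(1, 0.5, 0.5 * asy), a = asy * b, b = b)
    },
    stop("unknown family in helper")
  )
}

random_sj2p_free <- function() {
  K <- runif(1, 40, 200)
  r <- runif(1, 0.3, 1.5)
  L0 <- runif(1, 0.01, 0.3) * K
  # keep the logistic short of full saturation at j so the join is well posed
  j <- runif(1, 0.5, 0.9) * log((K - L0) / L0 * 20) / r
  sj2p_free_params(C = runif(1, 0.1, 0.9), K = K, L0 = L0,
                   k = runif(1, 0.02, 0.5), j = j, r = r)
}

# noiseless dataset from any truth over given ages (months)
exact_records <- function(truth, ages, measure = "pes") {
  cfg <- sim_config(truth, list(list(n = length(ages), ages = ages,
                                     sd = 0, measure = measure)),
                    seed = 1, noiseless = TRUE)
  simulate_cross_sectional(cfg)
}
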