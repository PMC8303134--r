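# shared fixture builders (all generated in code, nothing on disk)

noise_free_phantom <- function(alpha = 64, beta = 41, check = 0, seed = 1,
                               size = 256) {
  generate_phantom(phantom_spec(alpha_deg = alpha, beta_deg = beta,
                                check_deg = check, width_px = size,
                                height_px = size, speckle_sigma = 0,
                                seed = seed))
}

random_specs <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    phantom_spec(alpha_deg = runif(1, 5, 85), beta_deg = runif(1, 5, 85),
                 check_deg = runif(1, -30, 30), seed = i)
  })
}

random_landmark_set <- function() {
  repeat {
    p <- matrix(runif(10, 0, 200), ncol = 2)
    ls <- try(landmark_set(p[1, ], p[2, ], p[3, ], p[4, ], p[5, ]),
              silent = TRUE)
    if (!inherits(ls, "try-error")) return(ls)
  }
}

# independent angle oracle: explicit arc-cosine of normalised dot products
oracle_line_angle <- function(a1, a2, b1, b2) {
  u <- a2 - a1; v <- b2 - b1
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(u * v)))) * 180 / pi
}

reference_table <- function() contingency_2x2(320, 49, 49, 94)

# brute-force agreement oracle: expand the 2x2 table into per-item labels and
# count matches (p_o) and all marginal label pairings (p_e) explicitly
oracle_kappa_po_pe <- function(a, b, c, d) {
  ai <- c(rep("OK", a), rep("OK", b), rep("Error", c), rep("Error", d))
  hu <- c(rep("OK", a), rep("Error", b), rep("OK", c), rep("Error", d))
  n <- length(ai)
  po <- sum(ai == hu) / n
  pe <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    pe <- pe + (ai[i] == hu[j])
  }
  pe <- pe / n^2
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe))
}
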