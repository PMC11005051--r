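# Independent oracles shared by the unit and acceptance suites. These stay
# deliberately naive (loops, enumeration) and never call the implementation
# paths they check.

brute_ci <- function(delta, b) {
  num <- 0; Z <- 0
  n <- length(delta)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (delta[i] > delta[j]) {
      Z <- Z + 1
      if (b[i] > b[j]) num <- num + 1
      else if (b[i] == b[j]) num <- num + 0.5
    }
  }
  num / Z
}

brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  num <- 0
  for (p in pos) for (q in neg) {
    num <- num + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  num / (length(pos) * length(neg))
}

# Monte-Carlo signal-propagation ratio Var(output preact)/Var(input) for a
# relu main net whose parameters come from a freshly initialized
# hypernetwork; pooled over n_init head inits x n_draw standard-normal drugs.
signal_ratio <- function(depth, init = c("pwi", "naive"), n_init = 60,
                         n_draw = 40, d = 16) {
  init <- match.arg(init)
  spec <- main_net_spec(c(rep(d, depth), 1), activation = "relu")
  sch <- build_param_schema(spec)
  hspec <- hyper_net_spec(c(d, 32))
  outs <- unlist(lapply(seq_len(n_init), function(s) {
    st <- if (init == "pwi") {
      pwi_initialize(hspec, sch, var_t = 1, main_spec = spec, seed = s)
    } else {
      naive_initialize(hspec, sch, main_spec = spec, seed = s)
    }
    t_emb <- rnorm(d)
    qp <- distribute(hyper_forward(t_emb, st), sch)
    X <- matrix(rnorm(n_draw * d), n_draw, d)
    qsar_forward(X, qp, spec)
  }))
  var(outs)  # Var(x) = 1 by construction
}
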