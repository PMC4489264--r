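# Shared fixtures, computed once per test run.

helix20 <- make_helix(20)
model20 <- build_coarse_model(helix20)
params_encom <- potential_params()
params_anm <- potential_params("anm")
net20 <- build_network(model20, helix20, params_encom)
hess20 <- build_hessian(net20)
modes20 <- diagonalize(hess20)

dumbbell <- make_dumbbell()
dumbbell_model <- build_coarse_model(dumbbell)
dumbbell_modes <- diagonalize(build_hessian(
  build_network(dumbbell_model, dumbbell, params_encom)))

# exhaustive path-TSP optimum by enumeration (for small n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

path_total <- function(D, p) sum(D[cbind(p[-length(p)], p[-1])])

brute_force_path_optimum <- function(D) {
  min(vapply(all_perms(seq_len(nrow(D))), path_total, 0, D = D))
}

single_start_greedy_total <- function(D, start) {
  n <- nrow(D)
  visited <- logical(n); visited[start] <- TRUE
  cur <- start; total <- 0
  for (s in seq_len(n - 1L)) {
    cand <- which(!visited)
    nxt <- cand[which.min(D[cur, cand])]
    total <- total + D[cur, nxt]
    visited[nxt] <- TRUE; cur <- nxt
  }
  total
}
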