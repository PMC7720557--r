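# Shared fixtures and independent oracles used across the test files.

# rooted 4-taxon tree, tips at 0, nodes at 3, 6, root 10
ultra4 <- function() {
  timetree(c(5, 5, 6, 7, 6, 7, 0), c(0, 0, 0, 0, 3, 6, 10),
           c("A", "B", "C", "D"))
}

# 4-taxon tree with two fossil tips
fossil4 <- function() {
  timetree(c(5, 5, 6, 7, 6, 7, 0), c(0, 1.2, 4, 0, 3, 6, 10),
           c("A", "B", "C", "D"))
}

# 5-taxon tree with mixed tip ages
tree5 <- function() {
  timetree(c(6, 6, 7, 8, 9, 7, 8, 9, 0), c(0, 0.5, 0, 0.2, 0, 1, 2, 3, 5),
           c("A", "B", "C", "D", "E"))
}

# small mixed-symbol matrix on 5 taxa (binary + multistate + ambiguity)
matrix5 <- function() {
  cells <- rbind(A = c("0", "1", "{01}", "2"),
                 B = c("1", "0", "?", "0"),
                 C = c("0", "1", "1", "1"),
                 D = c("1", "1", "0", "2"),
                 E = c("0", "0", "-", "1"))
  morph_matrix(cells)
}

prior_check_calibrations <- function() {
  calibration_table(c("ext1", "ext2", "f1", "f2", "f3", "f4"),
                    c(0, 0, 80, 120, 160, 200),
                    c(0, 0, 95, 135, 175, 215))
}

# independent exhaustive-likelihood oracle: sum over all interior-node
# state assignments, including the Mkv constant-pattern correction
brute_mk_loglik <- function(tr, eff, mat, spec) {
  root <- which(tr$parent == 0L)
  acrv <- discretize_acrv(spec)
  freq_mix <- morphoclock:::freq_mixture_for
  total <- 0
  internal <- (tr$n_tip + 1L):length(tr$parent)
  for (j in seq_len(mat$n_char)) {
    k <- mat$k[j]
    fm <- freq_mix(k, spec)
    states_mat <- as.matrix(expand.grid(rep(list(1:k), length(internal))))
    pat <- mat$states[[j]]
    Lchar <- 0; Lconst <- 0
    for (f in seq_along(fm$weights)) for (rc in seq_len(nrow(acrv))) {
      w <- fm$weights[f] * acrv$weight[rc]
      P <- lapply(seq_along(tr$parent), function(v)
        if (tr$parent[v] == 0L) NULL else
          mk_transition_probability(k, eff[v] * acrv$rate[rc], fm$freqs[f, ]))
      for (row in seq_len(nrow(states_mat))) {
        s <- integer(length(tr$parent)); s[internal] <- states_mat[row, ]
        pr <- fm$freqs[f, s[root]]
        prc <- rep(pr, k)
        for (v in seq_along(tr$parent)) {
          if (tr$parent[v] == 0L) next
          sp_ <- s[tr$parent[v]]
          if (v <= tr$n_tip) {
            allowed <- pat[[match(tr$tip_label[v], mat$taxa)]]
            pv <- if (!length(allowed)) 1 else sum(P[[v]][sp_, allowed + 1L])
            prc <- prc * P[[v]][sp_, 1:k]
          } else {
            pv <- P[[v]][sp_, s[v]]
            prc <- prc * pv
          }
          pr <- pr * pv
        }
        Lchar <- Lchar + w * pr
        Lconst <- Lconst + w * sum(prc)
      }
    }
    total <- total + if (spec$correct) log(Lchar) - log1p(-Lconst) else log(Lchar)
  }
  total
}

# closed-form birth-death density oracle (rho = 1, psi = 0), conditioned on
# the root age and on >= 1 sampled extant lineage
bd_log_density_oracle <- function(tr, lambda, mu) {
  p0 <- function(t) mu * (1 - exp(-(lambda - mu) * t)) /
    (lambda - mu * exp(-(lambda - mu) * t))
  qq <- function(t) (lambda - mu)^2 * exp(-(lambda - mu) * t) /
    (lambda - mu * exp(-(lambda - mu) * t))^2
  root <- which(tr$parent == 0L)
  ages <- tr$age[(tr$n_tip + 1L):length(tr$parent)]
  internal_not_root <- setdiff((tr$n_tip + 1L):length(tr$parent), root)
  2 * log(qq(tr$age[root])) +
    sum(log(lambda * qq(tr$age[internal_not_root]))) -
    log(1 - p0(tr$age[root])^2)
}

yule_log_density_oracle <- function(tr, lambda) {
  root <- which(tr$parent == 0L)
  nr <- which(tr$parent > 0L)
  tot <- sum(tr$age[tr$parent[nr]] - tr$age[nr])
  (tr$n_tip - 2) * log(lambda) - lambda * tot
}

# deterministic pectinate starting tree for prior-sampling checks: internal
# nodes sit just above the tips they join (well below the root-prior
# offset), so the root age's full conditional is exactly its calibration
ladder_start_tree <- function(cal, root_age = 260) {
  n <- nrow(cal)
  tip_age <- (cal$age_min + cal$age_max) / 2
  ord <- order(tip_age)
  parent <- integer(2L * n - 1L)
  age <- numeric(2L * n - 1L)
  age[seq_len(n)] <- tip_age
  cur <- ord[1]
  for (i in seq_len(n - 1L)) {
    node <- n + i
    tipi <- ord[i + 1L]
    parent[cur] <- node
    parent[tipi] <- node
    age[node] <- if (i == n - 1L) root_age
                 else max(age[cur], age[tipi]) + 2
    cur <- node
  }
  timetree(parent, age, cal$taxon)
}
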