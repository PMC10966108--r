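# Shared fixtures: small pedigrees and an independent kinship oracle.

# Three-generation family: one founder couple, their two children with
# partners, and two grandchildren who are first cousins.
toy_pedigree <- function() {
  data.frame(
    id = 1:8,
    father_id = c(0, 0, 1, 1, 0, 0, 3, 5),
    mother_id = c(0, 0, 2, 2, 0, 0, 6, 4),
    sex = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
    generation = c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L)
  )
}

# Random small pedigree: founders plus individuals whose parents are drawn
# from earlier generations (relatives may mate, so inbreeding can occur).
random_pedigree <- function(n, n_founders = 4L, seed) {
  set.seed(seed)
  id <- seq_len(n)
  father <- mother <- integer(n)
  gen <- integer(n)
  sex <- integer(n)
  sex[seq_len(n_founders)] <- rep(c(1L, 2L), length.out = n_founders)
  for (i in seq((n_founders + 1L), n)) {
    males <- which(sex[seq_len(i - 1L)] == 1L)
    females <- which(sex[seq_len(i - 1L)] == 2L)
    f <- sample(males, 1L)
    m <- sample(females, 1L)
    father[i] <- f; mother[i] <- m
    gen[i] <- max(gen[f], gen[m]) + 1L
    sex[i] <- sample(c(1L, 2L), 1L)
  }
  data.frame(id = id, father_id = father, mother_id = mother,
             sex = sex, generation = gen)
}

# Independent kinship oracle: enumerate all ancestral paths from each
# individual; phi is the sum over common ancestors A and pairs of paths
# meeting only at A of (1/2)^(edges1 + edges2 + 1) * (1 + F_A).
oracle_kinship <- function(ped, i, j) {
  fa <- ped$father_id[match(seq_len(max(ped$id)), ped$id)]
  mo <- ped$mother_id[match(seq_len(max(ped$id)), ped$id)]
  paths_up <- function(x) {
    # all simple paths from x to each ancestor, including the trivial path
    out <- list(x)
    for (p in c(fa[x], mo[x])) {
      if (!is.na(p) && p != 0L)
        out <- c(out, lapply(paths_up(p), function(pp) c(x, pp)))
    }
    out
  }
  inbreeding <- function(x) {
    if (fa[x] == 0L || mo[x] == 0L) return(0)
    oracle_kinship(ped, fa[x], mo[x])
  }
  if (i == j) return(0.5 * (1 + inbreeding(i)))
  pi <- paths_up(i); pj <- paths_up(j)
  phi <- 0
  for (p1 in pi) {
    for (p2 in pj) {
      a <- p1[length(p1)]
      if (a != p2[length(p2)]) next
      if (length(intersect(p1, p2)) != 1L) next
      phi <- phi + 0.5^(length(p1) + length(p2) - 1) * (1 + inbreeding(a))
    }
  }
  phi
}
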