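#' Pedigree kinship coefficient
#'
#' Classic recursive kinship: for individuals `i`, `j` with `j` in the later
#' generation, `phi(i, j) = (phi(i, father_j) + phi(i, mother_j)) / 2`;
#' `phi(i, i) = (1 + phi(father_i, mother_i)) / 2`; founders are unrelated.
#' Missing parents (coded 0) contribute zero. Results are memoized within a
#' call, so vectors of pairs are cheap.
#'
#' @param ped Pedigree data frame (`id`, `father_id`, `mother_id`,
#'   `generation`; parents must precede children in generation order).
#' @param i,j Individual ids (equal-length vectors are paired elementwise).
#' @return Kinship coefficient(s) phi in `[0, 0.5]` for outbred pedigrees
#'   (above 0.5 only with inbreeding).
#' @examples
#' ped <- data.frame(id = 1:4, father_id = c(0, 0, 1, 1),
#'                   mother_id = c(0, 0, 2, 2), sex = c(1, 2, 1, 2),
#'                   generation = c(0, 0, 1, 1))
#' kinship_coefficient(ped, 3, 4) # full siblings: 0.25
#' @export
kinship_coefficient <- function(ped, i, j) {
  check_pedigree(ped)
  stopifnot(length(i) == length(j))
  pos <- function(ids) {
    m <- match(ids, ped$id)
    if (anyNA(m[ids != 0L])) stop("unknown individual id in pedigree query")
    m
  }
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  gen <- ped$generation
  memo <- new.env(hash = TRUE, parent = emptyenv())
  phi <- function(a, b) { # positional indices; NA = missing parent
    if (is.na(a) || is.na(b)) return(0)
    if (a == b) {
      key <- paste0(a, ":", a)
      if (!is.null(v <- memo[[key]])) return(v)
      v <- 0.5 * (1 + phi(fa[a], mo[a]))
      memo[[key]] <- v
      return(v)
    }
    key <- if (a < b) paste0(a, ":", b) else paste0(b, ":", a)
    if (!is.null(v <- memo[[key]])) return(v)
    # descend on the later-generation member, never an ancestor of the other
    if (gen[a] > gen[b]) { tmp <- a; a <- b; b <- tmp }
    v <- 0.5 * (phi(a, fa[b]) + phi(a, mo[b]))
    memo[[key]] <- v
    v
  }
  mapply(phi, pos(i), pos(j))
}

#' Classify a kinship coefficient into a relatedness degree
#'
#' Uses the standard inference ranges for genotype-based relatedness
#' (powers-of-two midpoints): above 0.3540 duplicate/monozygotic;
#' (0.1770, 0.3540] first degree; (0.0884, 0.1770] second degree;
#' (0.0442, 0.0884] third degree; at or below 0.0442, more distant or
#' unrelated.
#'
#' @param phi Kinship coefficient(s), non-negative.
#' @return Character vector of labels: `"duplicate-mz"`, `"first-degree"`,
#'   `"second-degree"`, `"third-degree"`, `"distant-unrelated"`.
#' @examples
#' classify_dyad(c(0.25, 0.125, 0.0625, 0.01))
#' @export
classify_dyad <- function(phi) {
  stopifnot(is.numeric(phi), all(phi >= 0))
  out <- character(length(phi))
  out[phi > 0.3540] <- "duplicate-mz"
  out[phi > 0.1770 & phi <= 0.3540] <- "first-degree"
  out[phi > 0.0884 & phi <= 0.1770] <- "second-degree"
  out[phi > 0.0442 & phi <= 0.0884] <- "third-degree"
  out[phi <= 0.0442] <- "distant-unrelated"
  out
}

# labels -> (kind, degree, affinal chain) used across the package
dyad_label_info <- function(label) {
  switch(label,
    "partner" = list(kind = "partner", degree = NA_integer_, chain = NULL),
    "parent-offspring" = list(kind = "blood", degree = 1L, chain = NULL),
    "full-sibling" = list(kind = "blood", degree = 1L, chain = NULL),
    "grandparent" = list(kind = "blood", degree = 2L, chain = NULL),
    "avuncular" = list(kind = "blood", degree = 2L, chain = NULL),
    "first-cousin" = list(kind = "blood", degree = 3L, chain = NULL),
    "great-grandparent" = list(kind = "blood", degree = 3L, chain = NULL),
    "grand-avuncular" = list(kind = "blood", degree = 3L, chain = NULL),
    "cousin-once-removed" = list(kind = "blood", degree = 4L, chain = NULL),
    "second-cousin" = list(kind = "blood", degree = 5L, chain = NULL),
    "sibling-in-law" = list(kind = "affinal", degree = NA_integer_,
                            chain = list(1, "partner")),
    "partner-parent" = list(kind = "affinal", degree = NA_integer_,
                            chain = list("partner", 1)),
    "co-parents-in-law" = list(kind = "affinal", degree = NA_integer_,
                               chain = list(1, "partner", 1)),
    stop("unknown dyad label: ", label)
  )
}

#' Enumerate family dyads from a pedigree
#'
#' Exhaustively lists partner dyads, blood dyads of degree 1--5 reachable in
#' the pedigree (parent-offspring, full siblings, grandparents, avuncular,
#' first cousins, great-grandparents, grand-avuncular, cousins once removed,
#' second cousins), and named affinal dyads (siblings-in-law, the partner's
#' parent, co-parents-in-law). Each unordered pair appears once per label.
#'
#' @param ped Pedigree data frame.
#' @param types Character vector of labels to enumerate (default all).
#' @return A data frame with columns `id_a`, `id_b`, `label`, `degree`
#'   (`NA` for partner and affinal dyads).
#' @export
enumerate_dyads <- function(ped, types = NULL) {
  check_pedigree(ped)
  all_types <- c("partner", "parent-offspring", "full-sibling", "grandparent",
                 "avuncular", "first-cousin", "great-grandparent",
                 "grand-avuncular", "cousin-once-removed", "second-cousin",
                 "sibling-in-law", "partner-parent", "co-parents-in-law")
  if (is.null(types)) types <- all_types
  stopifnot(all(types %in% all_types))

  id <- ped$id
  fa <- ped$father_id
  mo <- ped$mother_id
  has_par <- fa != 0L & mo != 0L
  kids_idx <- which(has_par)

  # couples (one row per distinct mother-father pair)
  ck <- paste(fa[kids_idx], mo[kids_idx])
  first_kid <- kids_idx[!duplicated(ck)]
  couples <- data.frame(f = fa[first_kid], m = mo[first_kid])

  # family-grouped children (all pairs = full siblings)
  fams <- split(id[kids_idx], ck)
  sib_a <- integer(0); sib_b <- integer(0)
  multi <- fams[lengths(fams) > 1L]
  if (length(multi)) {
    prs <- lapply(multi, function(v) {
      cm <- utils::combn(v, 2L)
      list(cm[1, ], cm[2, ])
    })
    sib_a <- unlist(lapply(prs, `[[`, 1L), use.names = FALSE)
    sib_b <- unlist(lapply(prs, `[[`, 2L), use.names = FALSE)
  }

  # children-of lookup (by either parent), positional for speed
  kid_ids <- id[kids_idx]
  par_pos <- c(match(fa[kids_idx], id), match(mo[kids_idx], id))
  by_pos <- split(rep(kid_ids, 2L), par_pos)
  children_of <- vector("list", length(id))
  children_of[as.integer(names(by_pos))] <- by_pos
  empty <- list(integer(0))
  kids_of <- function(x) {
    out <- children_of[match(x, id)]
    out[lengths(out) == 0L] <- empty
    out
  }
  parent_lookup <- function(x) { # returns data.frame of present parents
    i <- match(x, id)
    data.frame(child = x, fa = fa[i], mo = mo[i])
  }
  # expand (x, list-of-ids) into pairs
  expand_pairs <- function(x, lst) {
    lens <- lengths(lst)
    data.frame(a = rep(x, lens), b = unlist(lst, use.names = FALSE))
  }

  res <- list()
  add <- function(label, a, b) {
    if (!label %in% types || length(a) == 0L) return(invisible())
    keep <- !is.na(a) & !is.na(b) & a != 0L & b != 0L & a != b
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0L) return(invisible())
    lo <- pmin(a, b); hi <- pmax(a, b)
    d <- !duplicated(paste(lo, hi))
    res[[label]] <<- data.frame(id_a = lo[d], id_b = hi[d], label = label,
                                degree = dyad_label_info(label)$degree)
    invisible()
  }

  add("partner", couples$f, couples$m)
  add("parent-offspring", c(fa[kids_idx], mo[kids_idx]), rep(kid_ids, 2L))
  add("full-sibling", sib_a, sib_b)

  # grandparents & great-grandparents
  if (any(c("grandparent", "great-grandparent", "grand-avuncular") %in% types)) {
    p1 <- parent_lookup(kid_ids)
    par_all <- rbind(data.frame(child = p1$child, anc = p1$fa),
                     data.frame(child = p1$child, anc = p1$mo))
    g1 <- parent_lookup(par_all$anc)
    gp <- rbind(data.frame(child = par_all$child, anc = g1$fa),
                data.frame(child = par_all$child, anc = g1$mo))
    gp <- gp[!is.na(gp$anc) & gp$anc != 0L, ]
    add("grandparent", gp$anc, gp$child)
    g2 <- parent_lookup(gp$anc)
    ggp <- rbind(data.frame(child = gp$child, anc = g2$fa),
                 data.frame(child = gp$child, anc = g2$mo))
    ggp <- ggp[!is.na(ggp$anc) & ggp$anc != 0L, ]
    add("great-grandparent", ggp$anc, ggp$child)
  }

  # avuncular / cousins via sibling dyads
  if (length(sib_a) &&
      any(c("avuncular", "first-cousin", "grand-avuncular",
            "cousin-once-removed", "second-cousin") %in% types)) {
    ka <- kids_of(sib_a); kb <- kids_of(sib_b)
    av <- rbind(expand_pairs(sib_b, ka), expand_pairs(sib_a, kb))
    add("avuncular", av$a, av$b)
    # grand-avuncular: pair each aunt/uncle with the niece/nephew's children
    gav <- expand_pairs(av$a, kids_of(av$b))
    add("grand-avuncular", gav$a, gav$b)
    # first cousins: cross the two sibships' children
    lens_a <- lengths(ka); lens_b <- lengths(kb)
    reps <- lens_a * lens_b
    cz_a <- unlist(mapply(function(x, nb) rep(x, each = nb), ka, lens_b,
                          SIMPLIFY = FALSE), use.names = FALSE)
    cz_b <- unlist(mapply(function(y, na) rep(y, times = na), kb, lens_a,
                          SIMPLIFY = FALSE), use.names = FALSE)
    add("first-cousin", cz_a, cz_b)
    if (any(c("cousin-once-removed", "second-cousin") %in% types) &&
        length(cz_a)) {
      kca <- kids_of(cz_a); kcb <- kids_of(cz_b)
      cor1 <- rbind(expand_pairs(cz_b, kca), expand_pairs(cz_a, kcb))
      add("cousin-once-removed", cor1$a, cor1$b)
      la <- lengths(kca); lb <- lengths(kcb)
      sc_a <- unlist(mapply(function(x, nb) rep(x, each = nb), kca, lb,
                            SIMPLIFY = FALSE), use.names = FALSE)
      sc_b <- unlist(mapply(function(y, na) rep(y, times = na), kcb, la,
                            SIMPLIFY = FALSE), use.names = FALSE)
      add("second-cousin", sc_a, sc_b)
    }
  }

  # affinal dyads via couples
  if (any(c("sibling-in-law", "partner-parent", "co-parents-in-law")
          %in% types) && nrow(couples)) {
    sib_pos <- split(c(sib_b, sib_a), match(c(sib_a, sib_b), id))
    sib_of <- vector("list", length(id))
    sib_of[as.integer(names(sib_pos))] <- sib_pos
    sibs <- function(x) {
      out <- sib_of[match(x, id)]
      out[lengths(out) == 0L] <- list(integer(0))
      out
    }
    sil <- rbind(expand_pairs(couples$m, sibs(couples$f)),
                 expand_pairs(couples$f, sibs(couples$m)))
    add("sibling-in-law", sil$a, sil$b)
    pf <- parent_lookup(couples$f); pm <- parent_lookup(couples$m)
    pp <- rbind(data.frame(a = couples$m, b = pf$fa),
                data.frame(a = couples$m, b = pf$mo),
                data.frame(a = couples$f, b = pm$fa),
                data.frame(a = couples$f, b = pm$mo))
    add("partner-parent", pp$a, pp$b)
    cp <- rbind(data.frame(a = pf$fa, b = pm$fa),
                data.frame(a = pf$fa, b = pm$mo),
                data.frame(a = pf$mo, b = pm$fa),
                data.frame(a = pf$mo, b = pm$mo))
    add("co-parents-in-law", cp$a, cp$b)
  }

  out <- do.call(rbind, res[types[types %in% names(res)]])
  if (is.null(out))
    out <- data.frame(id_a = integer(0), id_b = integer(0),
                      label = character(0), degree = integer(0))
  rownames(out) <- NULL
  out
}

check_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "father_id", "mother_id", "generation") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicate ids in pedigree")
  for (col in c("father_id", "mother_id")) {
    pr <- match(ped[[col]], ped$id)
    known <- ped[[col]] != 0L
    if (anyNA(pr[known])) stop("parent id not present in pedigree")
    if (any(ped$generation[pr[known]] >= ped$generation[known]))
      stop("parents must precede children in generation order")
  }
  invisible(ped)
}
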