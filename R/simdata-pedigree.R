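#' Define a crossbreeding plan
#'
#' A plan names the purebred founder groups, optional composite founder
#' groups with their base-breed decomposition (e.g. Brangus = 3/8 Brahman +
#' 5/8 Angus), and a mating table executed generation by generation. Each
#' mating row draws sires and dams from previously created groups and gives
#' the offspring group a name that later rows may reference, so F1s,
#' backcrosses and advanced composites are all expressible.
#'
#' @param breeds character vector of base breed names.
#' @param composites named list; each element is a named numeric vector of
#'   base-breed fractions summing to 1.
#' @param matings data.frame with columns `gen` (integer >= 1), `group`
#'   (offspring group name), `sire_group`, `dam_group`, `n` (offspring
#'   count).
#' @return object of class `cross_plan`.
#' @examples
#' cross_plan(c("Angus", "Hereford"),
#'            matings = data.frame(gen = 1, group = "AxH",
#'                                 sire_group = "Angus",
#'                                 dam_group = "Hereford", n = 10))
#' @export
cross_plan <- function(breeds, composites = list(), matings) {
  stopifnot(is.character(breeds), length(breeds) >= 1)
  for (nm in names(composites)) {
    comp <- composites[[nm]]
    if (!all(names(comp) %in% breeds)) {
      stop("composite '", nm, "' references unknown breeds")
    }
    if (abs(sum(comp) - 1) > 1e-9) {
      stop("composite '", nm, "' fractions must sum to 1")
    }
  }
  need <- c("gen", "group", "sire_group", "dam_group", "n")
  stopifnot(all(need %in% names(matings)))
  known <- c(breeds, names(composites))
  for (i in seq_len(nrow(matings))) {
    avail <- c(known, matings$group[matings$gen < matings$gen[i]])
    for (g in c(matings$sire_group[i], matings$dam_group[i])) {
      if (!g %in% avail) {
        stop("mating row ", i, " references unknown group '", g, "'")
      }
    }
  }
  structure(list(breeds = breeds, composites = composites,
                 matings = matings), class = "cross_plan")
}

#' A default multibreed crossbreeding plan
#'
#' Builds a plan with within-breed purebred matings each generation (so
#' purebred lines accumulate relatedness and can carry runs of
#' homozygosity), F1 crosses between consecutive breed pairs, a backcross,
#' and composite-by-composite matings when composites are declared.
#'
#' @param breeds base breed names (>= 2 for crosses).
#' @param composites as in [cross_plan()].
#' @param n_generations generations of matings.
#' @param n_per_mating offspring per mating row.
#' @return a `cross_plan`.
#' @export
default_cross_plan <- function(breeds, composites = list(),
                               n_generations = 2, n_per_mating = 40) {
  rows <- list()
  add <- function(gen, group, s, d, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      gen = gen, group = group, sire_group = s, dam_group = d, n = n,
      stringsAsFactors = FALSE)
  }
  for (g in seq_len(n_generations)) {
    for (b in breeds) add(g, b, b, b, n_per_mating)
    for (cn in names(composites)) add(g, cn, cn, cn, n_per_mating)
    if (length(breeds) >= 2) {
      for (i in seq_len(length(breeds) - 1)) {
        f1 <- paste0("F1_", breeds[i], "_", breeds[i + 1])
        add(g, f1, breeds[i], breeds[i + 1], n_per_mating)
        if (g >= 2) {
          # backcross F1 females to the first parental breed
          add(g, paste0("BC_", breeds[i]), breeds[i], f1, n_per_mating)
        }
      }
      if (g >= 2 && length(breeds) >= 3) {
        f1 <- paste0("F1_", breeds[1], "_", breeds[2])
        add(g, paste0("X3_", breeds[3]), breeds[3], f1, n_per_mating)
      }
    }
  }
  cross_plan(breeds, composites, do.call(rbind, rows))
}

#' Simulate a pedigree with breed-composition bookkeeping
#'
#' Founders (generation 0) are created for every purebred and composite
#' group named in the plan; every non-founder's breed composition is the
#' average of its parents' compositions. Sires and dams are sampled (with
#' replacement across matings) from animals of the named group born in an
#' earlier generation, so parents always precede offspring. Birth season
#' index is the generation number.
#'
#' @param plan a [cross_plan()].
#' @param n_founders_per_breed founders created per founder group.
#' @param n_generations execute mating rows with `gen <=` this value.
#' @param seed integer seed.
#' @return object of class `herd_pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam`, `sex`, `gen`, `season`, `group`, carrying a
#'   `composition` attribute (animals x base breeds matrix).
#' @export
simulate_pedigree <- function(plan, n_founders_per_breed = 20,
                              n_generations = 2, seed = 1) {
  stopifnot(inherits(plan, "cross_plan"))
  if (n_founders_per_breed < 1) stop("zero founders")
  set.seed(seed)
  breeds <- plan$breeds
  founder_groups <- c(breeds, names(plan$composites))

  ids <- character(0); sire <- character(0); dam <- character(0)
  sex <- character(0); gen <- integer(0); group <- character(0)
  comp <- matrix(0, 0, length(breeds), dimnames = list(NULL, breeds))

  for (fg in founder_groups) {
    base <- stats::setNames(numeric(length(breeds)), breeds)
    if (fg %in% breeds) base[fg] <- 1 else {
      cc <- plan$composites[[fg]]
      base[names(cc)] <- cc
    }
    n <- n_founders_per_breed
    new_ids <- paste0(fg, "_0_", seq_len(n))
    ids <- c(ids, new_ids)
    sire <- c(sire, rep(NA_character_, n))
    dam <- c(dam, rep(NA_character_, n))
    # guarantee both sexes among founders of each group
    sx <- rep(c("M", "F"), length.out = n)[sample.int(n)]
    sex <- c(sex, sx)
    gen <- c(gen, rep(0L, n))
    group <- c(group, rep(fg, n))
    comp <- rbind(comp, matrix(rep(base, each = n), n, length(breeds),
                               dimnames = list(new_ids, breeds)))
  }

  mt <- plan$matings[plan$matings$gen <= n_generations, , drop = FALSE]
  for (g in sort(unique(mt$gen))) {
    rows <- mt[mt$gen == g, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      sires <- ids[group == r$sire_group & gen < g & sex == "M"]
      dams <- ids[group == r$dam_group & gen < g & sex == "F"]
      if (length(sires) == 0 || length(dams) == 0) {
        stop("no available ", if (length(sires) == 0) "sires" else "dams",
             " in group '",
             if (length(sires) == 0) r$sire_group else r$dam_group,
             "' at generation ", g)
      }
      s_pick <- sample(sires, r$n, replace = TRUE)
      d_pick <- sample(dams, r$n, replace = TRUE)
      new_ids <- paste0(r$group, "_", g, "_", length(ids) + seq_len(r$n))
      ids <- c(ids, new_ids)
      sire <- c(sire, s_pick)
      dam <- c(dam, d_pick)
      sex <- c(sex, sample(c("M", "F"), r$n, replace = TRUE))
      gen <- c(gen, rep(as.integer(g), r$n))
      group <- c(group, rep(r$group, r$n))
      newc <- (comp[s_pick, , drop = FALSE] + comp[d_pick, , drop = FALSE]) / 2
      rownames(newc) <- new_ids
      comp <- rbind(comp, newc)
    }
  }

  ped <- data.frame(id = ids, sire = sire, dam = dam, sex = sex,
                    gen = gen, season = gen, group = group,
                    stringsAsFactors = FALSE)
  stopifnot(max(abs(rowSums(comp) - 1)) < 1e-9)
  attr(ped, "composition") <- comp
  class(ped) <- c("herd_pedigree", "data.frame")
  ped
}

#' Construct a pedigree object from raw tables
#'
#' Validates ordering (parents precede offspring), sex codes, and the
#' composition matrix, then returns a `herd_pedigree`. Useful for
#' hand-built fixtures and for reading pedigrees back from CSV.
#'
#' @param df data.frame with columns id, sire, dam, sex, gen, season, group.
#' @param composition animals x breeds fraction matrix (rownames = id).
#' @return a `herd_pedigree`.
#' @export
herd_pedigree <- function(df, composition) {
  need <- c("id", "sire", "dam", "sex", "gen", "season", "group")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$id)) stop("duplicate animal ids")
  idx <- seq_along(df$id)
  for (col in c("sire", "dam")) {
    p <- match(df[[col]], df$id)
    bad <- !is.na(df[[col]]) & (is.na(p) | p >= idx)
    if (any(bad)) stop("parents must be listed before their offspring")
  }
  stopifnot(all(df$sex %in% c("M", "F")))
  composition <- as.matrix(composition)[df$id, , drop = FALSE]
  if (max(abs(rowSums(composition) - 1)) > 1e-9) {
    stop("breed compositions must sum to 1")
  }
  attr(df, "composition") <- composition
  class(df) <- c("herd_pedigree", "data.frame")
  df
}

#' Breed composition matrix of a pedigree
#' @param pedigree a `herd_pedigree`.
#' @return animals x breeds fraction matrix.
#' @export
breed_composition <- function(pedigree) {
  attr(pedigree, "composition")
}

#' Pedigree (tabular-method) inbreeding coefficients
#'
#' Classic recursive computation of the numerator relationship matrix on a
#' modestly sized pedigree; used as the reference the gene-dropping
#' simulator is checked against.
#'
#' @param pedigree a `herd_pedigree` (or data.frame with id/sire/dam).
#' @return named numeric vector of inbreeding coefficients F.
#' @export
pedigree_inbreeding <- function(pedigree) {
  id <- pedigree$id
  n <- length(id)
  si <- match(pedigree$sire, id)
  di <- match(pedigree$dam, id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (!is.na(s) && !is.na(d)) A[i, i] <- 1 + 0.5 * A[s, d]
    else A[i, i] <- 1
    if (i > 1) {
      js <- seq_len(i - 1)
      as_ <- if (!is.na(s)) A[js, s] else rep(0, i - 1)
      ad_ <- if (!is.na(d)) A[js, d] else rep(0, i - 1)
      A[js, i] <- A[i, js] <- 0.5 * (as_ + ad_)
    }
  }
  stats::setNames(diag(A) - 1, id)
}
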