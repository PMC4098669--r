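#' Multi-branch multiplex pedigree template
#'
#' Builds a three-generation pedigree: a founder couple, `branches`
#' children each married to an unrelated spouse, and `children` offspring
#' per branch of which the first `affected_per_branch` are affected. The
#' default (3 branches x 3 children, 2 affected each) mirrors a compact
#' multiplex family with 6 affected grandchildren.
#'
#' @param branches number of second-generation couples (default 3).
#' @param children offspring in the final sibships (default 3).
#' @param affected_per_branch affected offspring per final sibship
#'   (default 2).
#' @param generations pedigree depth, 3 or 4 (default 3). With 4
#'   generations each branch interposes one more couple, as in extended
#'   multiplex families.
#' @return a [Pedigree()].
#' @export
multiplex_pedigree <- function(branches = 3, children = 3,
                               affected_per_branch = 2, generations = 3) {
  stopifnot(affected_per_branch <= children, generations %in% c(3, 4))
  rows <- list(
    data.frame(id = c("F1", "F2"), father = NA, mother = NA,
               sex = c("male", "female"), affected = "unaffected"))
  for (b in seq_len(branches)) {
    cid <- sprintf("C%d", b); sid <- sprintf("S%d", b)
    csex <- if (b %% 2 == 1) "male" else "female"
    rows[[length(rows) + 1L]] <- data.frame(
      id = c(cid, sid),
      father = c("F1", NA), mother = c("F2", NA),
      sex = c(csex, if (csex == "male") "female" else "male"),
      affected = "unaffected")
    par_m <- if (csex == "male") cid else sid
    par_f <- if (csex == "male") sid else cid
    if (generations == 4) {
      did <- sprintf("D%d", b); tid <- sprintf("T%d", b)
      dsex <- if (b %% 2 == 1) "female" else "male"
      rows[[length(rows) + 1L]] <- data.frame(
        id = c(did, tid),
        father = c(par_m, NA), mother = c(par_f, NA),
        sex = c(dsex, if (dsex == "male") "female" else "male"),
        affected = "unaffected")
      par_m <- if (dsex == "male") did else tid
      par_f <- if (dsex == "male") tid else did
    }
    kids <- sprintf("G%d%d", b, seq_len(children))
    rows[[length(rows) + 1L]] <- data.frame(
      id = kids,
      father = par_m, mother = par_f,
      sex = rep(c("male", "female"), length.out = children),
      affected = ifelse(seq_len(children) <= affected_per_branch,
                        "affected", "unaffected"))
  }
  Pedigree(do.call(rbind, rows))
}

#' Simulation settings for a genotyped pedigree
#'
#' @param ped pedigree template (a [Pedigree()]).
#' @param map a [marker_map()] (genetic positions in cM drive Haldane
#'   recombination).
#' @param maf founder minor-allele frequencies: either a single range
#'   `c(lo, hi)` sampled uniformly per marker, or a vector of length
#'   `nrow(map)`.
#' @param planted optional planted risk segment: list with `chrom`,
#'   `start_bp`, `end_bp`, `carriers` (affected ids forced to inherit the
#'   founder risk haplotype over the interval) and optionally
#'   `noncarriers` (affected ids forced *not* to inherit it; defaults to
#'   the remaining affecteds).
#' @param missing_rate,error_rate per-genotype missingness and random
#'   genotyping error rates (default 0).
#' @return list of class `SimPedigreeSpec`.
#' @export
sim_pedigree_spec <- function(ped, map, maf = c(0.2, 0.5), planted = NULL,
                              missing_rate = 0, error_rate = 0) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  if (!is.null(planted)) {
    bad <- setdiff(planted$carriers, affected_ids(ped))
    if (length(bad))
      stop("planted carriers not affected pedigree members: ",
           paste(bad, collapse = ", "))
    if (is.null(planted$noncarriers))
      planted$noncarriers <- setdiff(affected_ids(ped), planted$carriers)
  }
  structure(list(ped = ped, map = map, maf = maf, planted = planted,
                 missing_rate = missing_rate, error_rate = error_rate),
            class = "SimPedigreeSpec")
}

# ancestor path from `from` up to `to` (inclusive), or NULL
.ancestor_path <- function(ped, from, to) {
  if (from == to) return(from)
  i <- match(from, ped$id)
  for (p in c(ped$father[i], ped$mother[i])) {
    if (is.na(p)) next
    sub <- .ancestor_path(ped, p, to)
    if (!is.null(sub)) return(c(from, sub))
  }
  NULL
}

#' Simulate genotypes through a pedigree
#'
#' Founder haplotypes are drawn from the per-marker allele frequencies;
#' every transmission is a recombinant gamete under the Haldane map
#' function (crossover probability `0.5 * (1 - exp(-2 d / 100))` between
#' markers `d` cM apart, no interference). When a risk segment is planted,
#' a founder ancestral to all designated carriers donates one haplotype
#' whose descent through each carrier's lineage is forced over the
#' interval; designated non-carrier affecteds are forced to receive the
#' other parental haplotype there. Genotyping errors (random re-draws) and
#' missingness are applied last, to the genotype matrix only — the truth
#' record keeps the error-free phased haplotypes.
#'
#' @param spec a [sim_pedigree_spec()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `ped`, `gm` (a [GenotypeMatrix()]) and `truth`: phased
#'   allele matrices `pat`/`mat`, founder-haplotype id matrices
#'   `pat_id`/`mat_id`, the `planted` description (with `risk_id` and
#'   `risk_founder`), and `maf`.
#' @export
simulate_pedigree <- function(spec, seed = 1) {
  set.seed(seed)
  ped <- spec$ped; map <- spec$map
  M <- nrow(map); n <- nrow(ped)
  maf <- if (length(spec$maf) == 2 && is.null(names(spec$maf)) &&
             M != 2) stats::runif(M, spec$maf[1], spec$maf[2]) else spec$maf
  stopifnot(length(maf) == M)

  founders <- ped$id[is_founder(ped)]
  planted <- spec$planted
  risk_founder <- NULL; paths <- list()
  if (!is.null(planted)) {
    cand <- founders
    for (carrier in planted$carriers) {
      cand <- Filter(function(f) !is.null(.ancestor_path(ped, carrier, f)),
                     cand)
    }
    if (!length(cand))
      stop("no founder is ancestral to every planted carrier")
    risk_founder <- cand[1]
    paths <- lapply(planted$carriers, function(carrier)
      rev(.ancestor_path(ped, carrier, risk_founder)))
    in_seg <- map$chrom == planted$chrom &
      map$pos_bp >= planted$start_bp & map$pos_bp <= planted$end_bp
    if (!any(in_seg)) stop("planted interval contains no markers")
  }

  hap <- function() as.integer(stats::runif(M) < maf)
  pat <- mat <- matrix(NA_integer_, n, M, dimnames = list(ped$id, NULL))
  pat_id <- mat_id <- matrix(NA_integer_, n, M, dimnames = list(ped$id, NULL))

  hid <- 0L
  for (f in founders) {
    pat[f, ] <- hap(); mat[f, ] <- hap()
    pat_id[f, ] <- (hid <- hid + 1L)
    mat_id[f, ] <- (hid <- hid + 1L)
  }
  risk_id <- if (!is.null(risk_founder)) pat_id[risk_founder, 1] else NA_integer_

  # recombination probability between adjacent markers (0.5 across chromosomes)
  r <- c(0.5, ifelse(map$chrom[-1] == map$chrom[-M],
                     0.5 * (1 - exp(-2 * diff(map$pos_cm) / 100)), 0.5))
  gamete_src <- function() {
    cross <- stats::runif(M) < r
    src <- cumsum(cross) %% 2L        # 0 = parent's paternal, 1 = maternal
    src
  }

  # process in an order where parents precede children
  order_ids <- character(0)
  remaining <- ped$id[!is_founder(ped)]
  done <- founders
  while (length(remaining)) {
    ready <- remaining[ped$father[match(remaining, ped$id)] %in% done &
                       ped$mother[match(remaining, ped$id)] %in% done]
    order_ids <- c(order_ids, ready)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }

  forced_from <- function(child) {
    # parent on a forcing path whose gamete to `child` must carry risk
    for (pth in paths) {
      i <- match(child, pth)
      if (!is.na(i) && i > 1L) return(pth[i - 1L])
    }
    NULL
  }

  for (id in order_ids) {
    i <- match(id, ped$id)
    for (side in c("father", "mother")) {
      par <- ped[[side]][i]
      src <- gamete_src()
      if (!is.null(planted)) {
        forcer <- forced_from(id)
        if (!is.null(forcer) && forcer == par) {
          # inherit the parent's risk-carrying haplotype over the interval
          on_pat <- all(pat_id[par, in_seg] == risk_id)
          on_mat <- all(mat_id[par, in_seg] == risk_id)
          if (!on_pat && !on_mat)
            stop("internal: forcing parent ", par, " lost the risk segment")
          risk_side <- if (on_pat) 0L else 1L
          src[in_seg] <- risk_side
          if (par == risk_founder) {
            # recombine at the interval boundaries of the founder's own
            # gametes, so the planted haplotype's IBD extent is exactly
            # the interval (flipping a flank preserves the Haldane
            # switch structure)
            same_chr <- which(map$chrom == planted$chrom)
            idxs <- which(in_seg)
            lo <- min(idxs); hi <- max(idxs)
            left <- same_chr[same_chr < lo]
            if (length(left) && src[max(left)] == risk_side)
              src[left] <- 1L - src[left]
            right <- same_chr[same_chr > hi]
            if (length(right) && src[min(right)] == risk_side)
              src[right] <- 1L - src[right]
          }
        } else if (id %in% planted$noncarriers &&
                   any(pat_id[par, in_seg] == risk_id |
                       mat_id[par, in_seg] == risk_id)) {
          # steer designated non-carriers away from the risk haplotype
          risk_side <- ifelse(pat_id[par, in_seg] == risk_id, 0L, 1L)
          src[in_seg] <- 1L - risk_side
        }
      }
      al <- ifelse(src == 0L, pat[par, ], mat[par, ])
      idv <- ifelse(src == 0L, pat_id[par, ], mat_id[par, ])
      if (side == "father") { pat[i, ] <- al; pat_id[i, ] <- idv }
      else { mat[i, ] <- al; mat_id[i, ] <- idv }
    }
  }

  geno <- pat + mat
  if (spec$error_rate > 0) {
    err <- matrix(stats::runif(n * M) < spec$error_rate, n, M)
    geno[err] <- sample(0:2, sum(err), replace = TRUE)
  }
  if (spec$missing_rate > 0)
    geno[matrix(stats::runif(n * M) < spec$missing_rate, n, M)] <- NA_integer_

  markers <- sprintf("m%04d", seq_len(M))
  map2 <- marker_map(markers, map$chrom, map$pos_bp, map$pos_cm)
  colnames(geno) <- markers
  colnames(pat) <- colnames(mat) <- markers
  colnames(pat_id) <- colnames(mat_id) <- markers
  alleles <- data.frame(marker = markers, a1 = "A", a2 = "B",
                        stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(geno, alleles, map2)

  if (!is.null(planted)) {
    planted$risk_id <- risk_id
    planted$risk_founder <- risk_founder
  }
  list(ped = ped, gm = gm,
       truth = list(pat = pat, mat = mat, pat_id = pat_id, mat_id = mat_id,
                    planted = planted, maf = maf))
}

#' Evenly spaced marker map for simulations
#'
#' @param n_markers markers per chromosome.
#' @param chrom chromosome label(s).
#' @param spacing_bp distance between adjacent markers (default 100 kb,
#'   i.e. 0.1 cM at 1 cM/Mb).
#' @return a [marker_map()].
#' @export
uniform_map <- function(n_markers, chrom = "1", spacing_bp = 1e5) {
  pos <- rep(seq_len(n_markers) * spacing_bp, length(chrom))
  ch <- rep(chrom, each = n_markers)
  marker_map(sprintf("m%04d", seq_along(pos)), ch, pos)
}
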