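#' Segments of haplotype sharing among a set of individuals
#'
#' Finds maximal runs of consecutive markers at which every individual in
#' `subset` carries an identical allele on at least one parental
#' chromosome, with a consistent chromosome choice per individual across
#' the whole run. Unresolved (`NA`) haplotype entries are wildcards: they
#' never break a run but do not count toward its marker support. A run
#' must be supported by at least `min_markers` markers at which sharing is
#' witnessed by every member. With `tolerance > 0`, up to that many
#' inconsistent markers are absorbed per run.
#'
#' @param phased a [phase_pedigree()] result.
#' @param subset character vector of individual ids (non-empty).
#' @param min_markers minimum number of fully witnessed markers (default 25).
#' @param tolerance number of inconsistent markers tolerated inside a run
#'   (default 0: a single opposite-allele mismatch breaks the segment).
#' @param max_vectors guard on the `2^|subset|` chromosome-choice vectors.
#' @return data frame of class `SharedSegments` with columns `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive, at the outermost supporting
#'   markers), `n_markers` (support), `carriers`. Sorted longest-first
#'   within chromosome, then leftmost.
#' @export
shared_segments <- function(phased, subset, min_markers = 25, tolerance = 0,
                            max_vectors = 4096) {
  if (length(subset) == 0L) stop("subset must be non-empty")
  missing_ids <- setdiff(subset, rownames(phased$pat))
  if (length(missing_ids))
    stop("individual(s) absent from phased set: ",
         paste(missing_ids, collapse = ", "))
  k <- length(subset)
  if (2^k > max_vectors)
    stop("subset of ", k, " members exceeds the chromosome-choice guard")

  map <- phased$map
  segs <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    P <- phased$pat[subset, idx, drop = FALSE]
    Mh <- phased$mat[subset, idx, drop = FALSE]
    found <- .scan_choice_vectors(P, Mh, min_markers, tolerance)
    if (nrow(found)) {
      found$chrom <- ch
      found$start_bp <- map$pos_bp[idx[found$start_i]]
      found$end_bp <- map$pos_bp[idx[found$end_i]]
      segs[[ch]] <- found
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start_i = integer(0), end_i = integer(0),
               n_markers = integer(0), chrom = character(0),
               start_bp = integer(0), end_bp = integer(0))
  out <- .drop_contained(out)
  out <- out[order(out$chrom, -(out$end_bp - out$start_bp), out$start_bp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out <- data.frame(chrom = out$chrom, start_bp = out$start_bp,
                    end_bp = out$end_bp, n_markers = out$n_markers,
                    carriers = rep(paste(subset, collapse = ","),
                                   nrow(out)),
                    stringsAsFactors = FALSE)
  class(out) <- c("SharedSegments", "data.frame")
  out
}

# Enumerate the 2^k per-member chromosome choices; for each, scan runs of
# consistency (all chosen non-NA entries equal) and report runs whose
# witnessed support (no NA, all equal) reaches min_markers.
.scan_choice_vectors <- function(P, Mh, min_markers, tolerance) {
  k <- nrow(P); M <- ncol(P)
  res <- list()
  for (v in 0:(2^k - 1)) {
    pick <- bitwAnd(bitwShiftR(v, seq_len(k) - 1L), 1L) == 1L
    ch <- P
    if (any(pick)) ch[pick, ] <- Mh[pick, , drop = FALSE]
    mxv <- rep(-Inf, M); mnv <- rep(Inf, M)
    for (i in seq_len(k)) {
      r <- ch[i, ]
      mxv <- pmax(mxv, ifelse(is.na(r), -Inf, r))
      mnv <- pmin(mnv, ifelse(is.na(r), Inf, r))
    }
    consistent <- mxv <= mnv
    witnessed <- consistent & is.finite(mxv) & is.finite(mnv) &
      colSums(is.na(ch)) == 0L
    for (w in .tolerant_windows(consistent, tolerance)) {
      wit <- which(witnessed[w[1]:w[2]]) + w[1] - 1L
      if (length(wit) >= min_markers)
        res[[length(res) + 1L]] <- c(wit[1], wit[length(wit)], length(wit))
    }
  }
  if (!length(res))
    return(data.frame(start_i = integer(0), end_i = integer(0),
                      n_markers = integer(0)))
  m <- unique(do.call(rbind, res))
  data.frame(start_i = m[, 1], end_i = m[, 2], n_markers = m[, 3])
}

# Maximal windows containing at most `tol` FALSE entries. tol = 0 reduces
# to maximal TRUE runs.
.tolerant_windows <- function(ok, tol) {
  M <- length(ok)
  if (M == 0L) return(list())
  if (tol == 0) {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    return(Map(c, starts[r$values], ends[r$values]))
  }
  out <- list()
  left <- 1L; bad <- 0L
  for (right in seq_len(M)) {
    if (!ok[right]) bad <- bad + 1L
    while (bad > tol) {
      if (!ok[left]) bad <- bad - 1L
      left <- left + 1L
    }
    if (right == M || (!ok[right + 1L] && bad == tol))
      out[[length(out) + 1L]] <- c(left, right)
  }
  out
}

# Remove segments strictly contained within another segment on the same
# chromosome (keeps the maximal ones).
.drop_contained <- function(segs) {
  if (nrow(segs) < 2L) return(segs)
  keep <- rep(TRUE, nrow(segs))
  for (i in seq_len(nrow(segs))) {
    within <- segs$chrom == segs$chrom[i] &
      segs$start_bp <= segs$start_bp[i] & segs$end_bp >= segs$end_bp[i]
    within[i] <- FALSE
    if (any(within & keep)) keep[i] <- FALSE
  }
  segs[keep, , drop = FALSE]
}

#' Sharing profile over affected-subset sizes
#'
#' Evaluates [shared_segments()] for every subset of the pedigree's
#' affected individuals of size `k`, for `k` from N (all affecteds) down to
#' `floor_k`. The single size-N comparison corresponds to N-of-N sharing;
#' size N-1 yields the N "leave-one-out" comparisons, and so on.
#'
#' @param ped a [Pedigree()].
#' @param phased a [phase_pedigree()] result covering the affecteds.
#' @param floor_k smallest subset size evaluated; default `N - 3`
#'   (never below 1).
#' @param min_markers,tolerance passed to [shared_segments()].
#' @param max_subsets refuse to enumerate when `choose(N, k)` exceeds this.
#' @return object of class `SharingProfile`: list with `segments` (data
#'   frame with `chrom`, `start_bp`, `end_bp`, `n_markers`, `k`, `n_affected`,
#'   `members`, `iteration`) and `n_subsets` (named count per k).
#' @export
sharing_profile <- function(ped, phased, floor_k = NULL, min_markers = 25,
                            tolerance = 0, max_subsets = 5000) {
  aff <- affected_ids(ped)
  aff <- aff[aff %in% rownames(phased$pat)]
  N <- length(aff)
  if (N == 0L) stop("pedigree has no phased affected individuals")
  if (is.null(floor_k)) floor_k <- max(N - 3L, 1L)
  if (floor_k > N) stop("floor_k exceeds the number of affecteds")

  rows <- list(); iter <- 0L
  n_subsets <- integer(0)
  for (k in seq(N, floor_k)) {
    if (choose(N, k) > max_subsets)
      stop("choose(", N, ", ", k, ") subsets exceed the configured cap")
    subs <- utils::combn(aff, k, simplify = FALSE)
    n_subsets[as.character(k)] <- length(subs)
    for (s in subs) {
      iter <- iter + 1L
      seg <- shared_segments(phased, s, min_markers = min_markers,
                             tolerance = tolerance)
      if (nrow(seg)) {
        seg$k <- k; seg$n_affected <- N
        seg$members <- paste(s, collapse = ",")
        seg$iteration <- iter
        seg$carriers <- NULL
        rows[[length(rows) + 1L]] <- as.data.frame(seg)
      }
    }
  }
  segments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), n_markers = integer(0), k = integer(0),
               n_affected = integer(0), members = character(0),
               iteration = integer(0), stringsAsFactors = FALSE)
  structure(list(segments = segments, n_subsets = n_subsets,
                 n_affected = N, floor_k = floor_k),
            class = "SharingProfile")
}

#' @export
print.SharingProfile <- function(x, ...) {
  cat(sprintf("SharingProfile: N = %d affecteds, k = %d..%d; %s subsets; %d segment(s)\n",
              x$n_affected, x$n_affected, x$floor_k,
              paste(rev(x$n_subsets), collapse = "+"), nrow(x$segments)))
  invisible(x)
}

#' Select candidate regions from per-pedigree sharing profiles
#'
#' Applies the region-selection rule used for choosing capture targets:
#' a segment qualifies when its sharing fraction k/N meets the minimum for
#' its pedigree class and its span meets `min_span_bp`. Segments from
#' two-generation pedigrees — where shared regions can be very large — are
#' retained only where they overlap a qualifying segment from a different
#' (extended) family, and then only the intersection is kept.
#'
#' @param profiles named list of [sharing_profile()] results; names are
#'   pedigree ids.
#' @param classes named character vector mapping pedigree id to
#'   `"extended"` or `"two_generation"`.
#' @param min_frac named numeric: minimum k/N per pedigree class
#'   (default `c(extended = 0.6, two_generation = 1)`).
#' @param min_span_bp minimum segment span in bp (default 0).
#' @return data frame with `chrom`, `start_bp`, `end_bp`, `sharing`
#'   ("k of N"), `pedigree`.
#' @export
select_regions <- function(profiles, classes,
                           min_frac = c(extended = 0.6, two_generation = 1),
                           min_span_bp = 0) {
  pull <- function(cls) {
    ids <- names(profiles)[classes[names(profiles)] == cls]
    rows <- lapply(ids, function(pid) {
      s <- profiles[[pid]]$segments
      if (nrow(s) == 0L) return(NULL)
      s <- s[s$k / s$n_affected >= min_frac[[cls]] &
             (s$end_bp - s$start_bp + 1L) >= min_span_bp, , drop = FALSE]
      if (nrow(s) == 0L) return(NULL)
      s$pedigree <- pid
      s
    })
    do.call(rbind, rows)
  }
  ext <- pull("extended")
  two <- pull("two_generation")

  fmt <- function(s) data.frame(
    chrom = s$chrom, start_bp = s$start_bp, end_bp = s$end_bp,
    sharing = paste(s$k, "of", s$n_affected), pedigree = s$pedigree,
    stringsAsFactors = FALSE)

  out <- if (!is.null(ext) && nrow(ext)) fmt(ext) else
    data.frame(chrom = character(0), start_bp = integer(0),
               end_bp = integer(0), sharing = character(0),
               pedigree = character(0), stringsAsFactors = FALSE)

  if (!is.null(two) && nrow(two) && nrow(out)) {
    gr_two <- GenomicRanges::GRanges(two$chrom,
               IRanges::IRanges(two$start_bp, two$end_bp))
    gr_ext <- GenomicRanges::GRanges(out$chrom,
               IRanges::IRanges(out$start_bp, out$end_bp))
    hits <- GenomicRanges::findOverlaps(gr_two, gr_ext)
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      other <- two$pedigree[qi] != out$pedigree[si]
      qi <- qi[other]; si <- si[other]
      if (length(qi)) {
        inter <- IRanges::pintersect(IRanges::ranges(gr_two)[qi],
                                     IRanges::ranges(gr_ext)[si])
        add <- data.frame(
          chrom = two$chrom[qi],
          start_bp = IRanges::start(inter), end_bp = IRanges::end(inter),
          sharing = paste(two$k[qi], "of", two$n_affected[qi]),
          pedigree = two$pedigree[qi], stringsAsFactors = FALSE)
        out <- rbind(out, unique(add))
      }
    }
  }
  rownames(out) <- NULL
  out
}
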