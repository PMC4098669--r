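#' Pedigree container
#'
#' A `Pedigree` is a validated data frame with one row per individual and
#' columns `fid` (family id), `id`, `father`, `mother` (NA for founders),
#' `sex` (`"male"`, `"female"` or `"unknown"`) and `affected` (`"affected"`,
#' `"unaffected"` or `"unknown"`). Non-founders must reference two parents
#' that are present in the same family; parentage must be acyclic and sexes
#' consistent with parental roles.
#'
#' @param df data frame with the columns above (`fid` optional, default "F1").
#' @return An object of class `Pedigree` (a data frame).
#' @examples
#' trio <- Pedigree(data.frame(
#'   id = c("dad", "mom", "kid"),
#'   father = c(NA, NA, "dad"), mother = c(NA, NA, "mom"),
#'   sex = c("male", "female", "male"),
#'   affected = c("unaffected", "unaffected", "affected")))
#' n_founders(trio)
#' @export
Pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$fid)) df$fid <- "F1"
  needed <- c("fid", "id", "father", "mother", "sex", "affected")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("Pedigree is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, needed]
  for (col in needed) df[[col]] <- as.character(df[[col]])
  df$father[df$father %in% c("", "0")] <- NA_character_
  df$mother[df$mother %in% c("", "0")] <- NA_character_

  dup <- df$id[duplicated(df$id)]
  if (length(dup))
    stop("duplicated individual id(s): ", paste(unique(dup), collapse = ", "))

  half <- xor(is.na(df$father), is.na(df$mother))
  if (any(half))
    stop("individual(s) with exactly one known parent: ",
         paste(df$id[half], collapse = ", "))

  for (p in c("father", "mother")) {
    bad <- !is.na(df[[p]]) & !(df[[p]] %in% df$id)
    if (any(bad))
      stop("child references absent ", p, ": ",
           paste(unique(df[[p]][bad]), collapse = ", "))
  }

  ok_sex <- c("male", "female", "unknown")
  df$sex[is.na(df$sex)] <- "unknown"
  if (!all(df$sex %in% ok_sex)) stop("sex must be one of ", paste(ok_sex, collapse = "/"))
  df$affected[is.na(df$affected)] <- "unknown"
  ok_aff <- c("affected", "unaffected", "unknown")
  if (!all(df$affected %in% ok_aff))
    stop("affected must be one of ", paste(ok_aff, collapse = "/"))

  # fathers must be male, mothers female (unknown is upgraded, mismatch fatal)
  fa <- unique(stats::na.omit(df$father)); mo <- unique(stats::na.omit(df$mother))
  bad_fa <- fa[df$sex[match(fa, df$id)] == "female"]
  bad_mo <- mo[df$sex[match(mo, df$id)] == "male"]
  if (length(bad_fa) || length(bad_mo))
    stop("parental roles inconsistent with sex: ",
         paste(c(bad_fa, bad_mo), collapse = ", "))
  df$sex[df$id %in% fa & df$sex == "unknown"] <- "male"
  df$sex[df$id %in% mo & df$sex == "unknown"] <- "female"

  if (.has_parent_cycle(df)) stop("pedigree parentage contains a cycle")

  class(df) <- c("Pedigree", "data.frame")
  df
}

.has_parent_cycle <- function(df) {
  # depth-first over parent links; a cycle exists iff some id is its own ancestor
  parents <- function(i) stats::na.omit(c(df$father[i], df$mother[i]))
  n <- nrow(df)
  state <- integer(n)  # 0 unvisited, 1 in stack, 2 done
  names(state) <- df$id
  visit <- function(id) {
    i <- match(id, df$id)
    if (state[i] == 1L) return(TRUE)
    if (state[i] == 2L) return(FALSE)
    state[i] <<- 1L
    for (p in parents(i)) if (visit(p)) return(TRUE)
    state[i] <<- 2L
    FALSE
  }
  for (id in df$id) if (visit(id)) return(TRUE)
  FALSE
}

#' @rdname Pedigree
#' @param ped a `Pedigree`.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' @rdname Pedigree
#' @export
n_founders <- function(ped) sum(is_founder(ped))

#' Affected members of a pedigree
#' @param ped a `Pedigree`.
#' @return character vector of ids with affection status `"affected"`.
#' @export
affected_ids <- function(ped) ped$id[ped$affected == "affected"]

#' @export
print.Pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals (%d founders, %d affected)\n",
              nrow(x), n_founders(x), length(affected_ids(x))))
  print.data.frame(x, ...)
  invisible(x)
}

# All (child, father, mother) index triples with both parents known.
.trios <- function(ped) {
  kid <- which(!is.na(ped$father))
  data.frame(child = kid,
             father = match(ped$father[kid], ped$id),
             mother = match(ped$mother[kid], ped$id))
}
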