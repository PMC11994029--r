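#' Define a species pool
#'
#' A species pool is an ordered set of community members. The order is
#' canonical: it fixes how resident and co-invader sets are sorted inside
#' treatment identifiers, so that enumeration is fully deterministic.
#'
#' @param labels Character vector of distinct, non-empty species labels.
#'   Defaults to the five-member soil community used throughout the package:
#'   Achromobacter (A), Ochrobactrum (O), Pseudomonas (P), Stenotrophomonas
#'   (S) and Variovorax (V).
#' @return A character vector of class `"species_pool"`.
#' @examples
#' species_pool()
#' species_pool(c("sp1", "sp2", "sp3"))
#' @export
species_pool <- function(labels = c("A", "O", "P", "S", "V")) {
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop("a species pool needs at least 2 species", call. = FALSE)
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop("species labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("species labels must be unique", call. = FALSE)
  }
  structure(labels, class = "species_pool")
}

as_pool <- function(pool) {
  if (inherits(pool, "species_pool")) pool else species_pool(pool)
}

## Sort a set of labels into canonical (pool) order and serialize it by
## concatenation, the convention used in treatment identifiers and CSVs
## (e.g. residents {P, A} of the default pool -> "AP").
sort_by_pool <- function(labels, pool) {
  labels[order(match(labels, pool))]
}

serialize_set <- function(labels, pool) {
  paste(sort_by_pool(labels, pool), collapse = "")
}

## Inverse of serialize_set. Only unambiguous for single-character labels;
## multi-character pools must keep sets as lists and never round-trip
## through the concatenated form.
split_set <- function(s, pool) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  if (any(nchar(pool) != 1L)) {
    stop("concatenated species sets are only supported for single-character labels",
         call. = FALSE)
  }
  out <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(out, pool)
  if (length(bad)) {
    stop("unknown species label(s) in set '", s, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Deterministic treatment identifier
#'
#' Builds the canonical id `"<focal>_into_<residents>"` for single invasions
#' and `"<focal>_into_<residents>_with_<co-invaders>"` for co-invasions,
#' with both sets sorted in pool order (e.g. `"V_into_AP_with_OS"`).
#'
#' @param focal Focal invader label.
#' @param residents Character vector of resident labels.
#' @param co_invaders Character vector of co-invader labels (may be empty).
#' @param pool The species pool (defines sorting).
#' @return A single string.
#' @export
treatment_id <- function(focal, residents, co_invaders = character(0), pool) {
  pool <- as_pool(pool)
  id <- paste0(focal, "_into_", serialize_set(residents, pool))
  if (length(co_invaders)) {
    id <- paste0(id, "_with_", serialize_set(co_invaders, pool))
  }
  id
}

new_invasion_design <- function(rows, pool) {
  df <- do.call(rbind.data.frame, c(rows, list(stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  structure(df, pool = as.character(pool),
            class = c("invasion_design", "data.frame"))
}

check_richness <- function(richness, n, what) {
  if (length(richness) == 1L) richness <- c(richness, richness)
  if (length(richness) != 2L || anyNA(richness) ||
      richness[1] < 1L || richness[2] > n - 1L || richness[1] > richness[2]) {
    stop("invalid invasion design: ", what, " richness must satisfy 1 <= min <= max <= ",
         n - 1L, " (pool size - 1); got [", paste(richness, collapse = ", "), "]",
         call. = FALSE)
  }
  as.integer(richness)
}

#' Enumerate the co-invasion design
#'
#' Enumerates every multi-species invasion treatment over a pool: for each
#' invader subset of the requested richness, every member of the subset in
#' turn is the focal invader, the remaining subset members are co-invaders,
#' and the rest of the pool is the resident community. Total community
#' richness is therefore always the full pool (all species present), the
#' design of the five-species co-invasion experiment: over 5 species with
#' invader richness 2-4 this gives 70 treatments, 14 per focal species.
#'
#' @param pool A [species_pool()] (or character vector coerced to one).
#' @param invader_richness Length-2 integer vector `c(min, max)` of invader
#'   subset sizes (a single value is recycled); must lie in
#'   `[1, pool size - 1]`.
#' @param replicates Number of replicates per treatment (default 6).
#' @return A data frame of class `"invasion_design"` with columns
#'   `treatment_id`, `focal`, `residents`, `co_invaders`, `invasion_type`,
#'   `replicates`. Sets are serialized as concatenated pool-sorted labels.
#'   Ordering is deterministic: invader richness ascending, then invader
#'   subsets and focals in pool order.
#' @examples
#' d <- design_co_invasion(species_pool(), invader_richness = c(2, 4))
#' nrow(d)              # 70
#' table(d$focal)       # 14 each
#' @seealso [design_single_invasion()], [pair_by_residents()]
#' @export
design_co_invasion <- function(pool = species_pool(),
                               invader_richness = c(2, 4),
                               replicates = 6) {
  pool <- as_pool(pool)
  n <- length(pool)
  richness <- check_richness(invader_richness, n, "invader")
  replicates <- check_replicates(replicates)
  rows <- list()
  for (k in seq(richness[1], richness[2])) {
    subsets <- utils::combn(seq_len(n), k, simplify = FALSE)
    for (idx in subsets) {
      invaders <- pool[idx]
      residents <- pool[-idx]
      for (focal in invaders) {
        co <- setdiff(invaders, focal)
        rows[[length(rows) + 1L]] <- list(
          treatment_id = treatment_id(focal, residents, co, pool),
          focal = focal,
          residents = serialize_set(residents, pool),
          co_invaders = serialize_set(co, pool),
          invasion_type = "co",
          replicates = replicates
        )
      }
    }
  }
  new_invasion_design(rows, pool)
}

#' Enumerate the single-invasion design
#'
#' Enumerates every single-species invasion treatment: each focal species is
#' invaded from rare into every resident subset (drawn from the remaining
#' pool) of the requested richness. Over 5 species with resident richness
#' 1-4 this gives 75 treatments (5 focals x 15 resident subsets), the full
#' decomposition design against which co-invasion treatments are paired.
#'
#' @inheritParams design_co_invasion
#' @param resident_richness Length-2 integer vector `c(min, max)` of
#'   resident subset sizes; must lie in `[1, pool size - 1]`.
#' @return An `"invasion_design"` data frame (see [design_co_invasion()]);
#'   `co_invaders` is empty and `invasion_type` is `"single"` throughout.
#' @examples
#' nrow(design_single_invasion(species_pool()))  # 75
#' @export
design_single_invasion <- function(pool = species_pool(),
                                   resident_richness = c(1, 4),
                                   replicates = 6) {
  pool <- as_pool(pool)
  n <- length(pool)
  richness <- check_richness(resident_richness, n, "resident")
  replicates <- check_replicates(replicates)
  rows <- list()
  for (focal in pool) {
    others <- setdiff(pool, focal)
    for (k in seq(richness[1], richness[2])) {
      subsets <- utils::combn(seq_along(others), k, simplify = FALSE)
      for (idx in subsets) {
        residents <- others[idx]
        rows[[length(rows) + 1L]] <- list(
          treatment_id = treatment_id(focal, residents, character(0), pool),
          focal = focal,
          residents = serialize_set(residents, pool),
          co_invaders = "",
          invasion_type = "single",
          replicates = replicates
        )
      }
    }
  }
  new_invasion_design(rows, pool)
}

check_replicates <- function(replicates) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("replicates must be a positive integer", call. = FALSE)
  }
  replicates
}

#' Pair co-invasion treatments with their single-invasion counterparts
#'
#' Each co-invasion treatment is matched to the unique single-invasion
#' treatment with the same focal species AND the same resident community,
#' the comparison at the heart of single- versus multi-species invasion
#' analyses (e.g. V invading residents {A, P} with co-invaders {O, S} pairs
#' with V invading residents {A, P} alone).
#'
#' @param co,single `"invasion_design"` data frames (or data frames with the
#'   same columns) drawn from the same pool.
#' @return A data frame with one row per co-invasion treatment: columns
#'   `focal`, `residents`, `co_treatment_id`, `single_treatment_id` (`NA`
#'   when no counterpart exists) and `paired` (logical).
#' @examples
#' pairs <- pair_by_residents(design_co_invasion(), design_single_invasion())
#' sum(pairs$paired)  # 70: every co treatment has a counterpart
#' @export
pair_by_residents <- function(co, single) {
  for (nm in c("treatment_id", "focal", "residents")) {
    if (!nm %in% names(co) || !nm %in% names(single)) {
      stop("design tables need columns treatment_id, focal, residents", call. = FALSE)
    }
  }
  key_co <- paste(co$focal, co$residents, sep = "|")
  key_single <- paste(single$focal, single$residents, sep = "|")
  if (anyDuplicated(key_co)) {
    stop("ambiguous design: duplicate (focal, residents) in co-invasion list: ",
         paste(unique(key_co[duplicated(key_co)]), collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(key_single)) {
    stop("ambiguous design: duplicate (focal, residents) in single-invasion list: ",
         paste(unique(key_single[duplicated(key_single)]), collapse = "; "), call. = FALSE)
  }
  hit <- match(key_co, key_single)
  out <- data.frame(
    focal = co$focal,
    residents = co$residents,
    co_treatment_id = co$treatment_id,
    single_treatment_id = ifelse(is.na(hit), NA_character_, single$treatment_id[hit]),
    paired = !is.na(hit),
    stringsAsFactors = FALSE
  )
  out
}

#' @export
print.invasion_design <- function(x, ...) {
  pool <- attr(x, "pool")
  cat("Invasion assay design: ", nrow(x), " treatments over pool {",
      paste(pool, collapse = ", "), "}\n", sep = "")
  tab <- table(x$invasion_type)
  for (ty in names(tab)) cat("  ", ty, " invasion: ", tab[[ty]], " treatments\n", sep = "")
  cat("  replicates per treatment: ", paste(unique(x$replicates), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read/write design tables
#'
#' Design tables travel as plain CSV with columns `treatment_id`, `focal`,
#' `residents`, `co_invaders`, `invasion_type`, `replicates`.
#'
#' @param design An `"invasion_design"` data frame.
#' @param path File path.
#' @param pool Species pool to attach when reading (defaults to the labels
#'   present in the file, in first-appearance order of `focal`).
#' @return `read_design()` returns an `"invasion_design"` data frame;
#'   `write_design()` returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, pool = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(co_invaders = "character",
                                       residents = "character"))
  df$co_invaders[is.na(df$co_invaders)] <- ""
  if (is.null(pool)) pool <- unique(df$focal)
  structure(df, pool = as.character(pool),
            class = c("invasion_design", "data.frame"))
}
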