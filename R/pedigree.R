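#' Generate a breeding-design pedigree
#'
#' Builds the family scaffold of a line: generation 0 holds `2 * n_pairs`
#' founders (one male and one female per founding pair); every later
#' generation holds the realized offspring of `n_pairs` families, with
#' offspring counts drawn from `offspring` and sexes assigned i.i.d.
#' Bernoulli(1/2).  Families in which one sex is absent are redrawn (the real
#' design always had a breedable male and female per family); after
#' `max_retry` failures an error is raised.  Breeder slots (which offspring
#' actually breed, and the sire/dam ids) are left unassigned here and filled
#' by [run_experiment()]'s selection rule.
#'
#' @param n_pairs breeding pairs per generation (>= 2).
#' @param n_generations number of bred generations after the founders.
#' @param offspring offspring count per family: a single number (constant
#'   litter size) or `list(type = "poisson", mean = m)`.  Mean must be >= 2.
#' @param seed optional integer seed.
#' @param max_retry sex redraws allowed per family.
#' @return A `pedigree`: data.frame with columns `id`, `family`, `sex`
#'   ("M"/"F"), `generation`; attributes `n_pairs` and `seed`.
#' @examples
#' ped <- make_pedigree(16, 17, 12, seed = 1)
#' table(ped$generation)[1:3]
#' @export
make_pedigree <- function(n_pairs, n_generations, offspring = 12, seed = NULL,
                          max_retry = 100L) {
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  if (n_generations < 1) stop("n_generations must be >= 1")
  spec <- offspring_spec(offspring)
  if (spec$mean < 2) stop("offspring distribution must have mean >= 2")
  if (!is.null(seed)) withr::local_seed(seed)

  rows <- list()
  # founders: one M + one F per pair
  rows[[1]] <- data.frame(
    id = seq_len(2L * n_pairs),
    family = rep(seq_len(n_pairs), each = 2L),
    sex = rep(c("M", "F"), n_pairs),
    generation = 0L, stringsAsFactors = FALSE)
  next_id <- 2L * n_pairs + 1L
  for (g in seq_len(n_generations)) {
    n_off <- vapply(seq_len(n_pairs), function(f) draw_offspring(spec), 0L)
    if (any(n_off < 2))
      stop(sprintf("a family at generation %d has fewer than 2 offspring", g))
    fam <- rep(seq_len(n_pairs), n_off)
    sexes <- ifelse(stats::runif(sum(n_off)) < 0.5, "M", "F")
    # redraw families lacking one sex
    for (f in seq_len(n_pairs)) {
      idx <- which(fam == f)
      if (length(unique(sexes[idx])) < 2)
        sexes[idx] <- draw_sexes(length(idx), max_retry, f, g)
    }
    rows[[g + 1L]] <- data.frame(
      id = seq.int(next_id, length.out = sum(n_off)),
      family = fam, sex = sexes, generation = g, stringsAsFactors = FALSE)
    next_id <- next_id + sum(n_off)
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  attr(ped, "n_pairs") <- as.integer(n_pairs)
  attr(ped, "seed") <- seed
  class(ped) <- c("pedigree", "data.frame")
  ped
}

offspring_spec <- function(offspring) {
  if (is.numeric(offspring) && length(offspring) == 1)
    return(list(type = "constant", mean = as.numeric(offspring)))
  if (is.list(offspring) && !is.null(offspring$type))
    return(list(type = match.arg(offspring$type, c("constant", "poisson")),
                mean = as.numeric(offspring$mean)))
  stop("offspring must be a number or list(type=, mean=)")
}

draw_offspring <- function(spec) {
  if (spec$type == "constant") return(as.integer(round(spec$mean)))
  as.integer(stats::rpois(1, spec$mean))
}

draw_sexes <- function(n_off, max_retry, fam, gen) {
  for (i in seq_len(max_retry)) {
    sexes <- ifelse(stats::runif(n_off) < 0.5, "M", "F")
    if (any(sexes == "M") && any(sexes == "F")) return(sexes)
  }
  stop(sprintf("family %d at generation %d lacks one sex after %d redraws",
               fam, gen, max_retry))
}

#' Write / read a pedigree as tab-separated text
#'
#' Columns: id, sire, dam, sex, generation, line.  Sire/dam are `NA` for
#' founders and for pedigrees whose breeders have not yet been assigned by
#' [run_experiment()].
#' @param ped a `pedigree` (possibly realized, with `sire`/`dam` columns).
#' @param path output file.
#' @param line line label to store.
#' @export
write_pedigree <- function(ped, path, line = "L1") {
  df <- as.data.frame(ped)
  if (is.null(df$sire)) df$sire <- NA_integer_
  if (is.null(df$dam)) df$dam <- NA_integer_
  out <- df[, c("id", "sire", "dam", "sex", "generation")]
  out$line <- line
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Check pedigree structural invariants
#'
#' Verifies acyclicity (no individual is its own ancestor) and generation
#' ordering (parents belong to the previous generation), for realized
#' pedigrees with sire/dam columns; structural checks only for unrealized
#' ones.
#' @param ped a pedigree data.frame.
#' @return TRUE (invisibly) or an error.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(ped$generation >= 0), all(ped$sex %in% c("M", "F")))
  if (!is.null(ped$sire)) {
    gen <- ped$generation[match(ped$sire, ped$id)]
    ok <- is.na(ped$sire) | (gen == ped$generation - 1L)
    if (!all(ok, na.rm = TRUE)) stop("sire not from previous generation")
    gen <- ped$generation[match(ped$dam, ped$id)]
    ok <- is.na(ped$dam) | (gen == ped$generation - 1L)
    if (!all(ok, na.rm = TRUE)) stop("dam not from previous generation")
    # generation ordering implies acyclicity; still check ids distinct
  }
  if (anyDuplicated(ped$id)) stop("duplicate ids")
  invisible(TRUE)
}
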