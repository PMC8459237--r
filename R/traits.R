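#' Define a functional trait
#'
#' A trait is a feature or behaviour of a species that affects or responds to
#' its environment; a modality is one of its discrete scoring levels.  Traits
#' are either `ordered` (modalities form a gradient, e.g. body-size classes)
#' or `categorical` (no ordering among modalities).
#'
#' @param name trait identifier.
#' @param kind `"ordered"` or `"categorical"`.
#' @param levels character vector of modality labels; for ordered traits the
#'   order of this vector is the ordering of the gradient.
#' @return An object of class `trait_spec`.
#' @examples
#' trait_spec("external protection", "ordered",
#'            c("soft bodied", "moderately protected", "well protected"))
#' @export
trait_spec <- function(name, kind = c("categorical", "ordered"), levels) {
  kind <- match.arg(kind)
  name <- as.character(name)
  levels <- as.character(levels)
  if (length(name) != 1L || !nzchar(name))
    stop("trait 'name' must be a single non-empty string")
  if (length(levels) == 0L)
    stop("trait '", name, "': 'levels' must be non-empty")
  if (anyDuplicated(levels))
    stop("trait '", name, "': duplicated modality labels")
  if (kind == "ordered" && length(levels) < 2L)
    stop("trait '", name, "': an ordered trait needs at least 2 levels")
  structure(list(name = name, kind = kind, levels = levels),
            class = "trait_spec")
}

#' @export
print.trait_spec <- function(x, ...) {
  sep <- if (x$kind == "ordered") " < " else ", "
  cat(sprintf("trait '%s' (%s): %s\n", x$name, x$kind,
              paste(x$levels, collapse = sep)))
  invisible(x)
}

#' Default trait set for vent colonist communities
#'
#' The eight functional traits scored for East Pacific Rise vent colonists,
#' with their published modality lists: maximum adult body size, habitat
#' complexity, trophic mode, feeding method, relative adult mobility,
#' external protection, larval development and reproductive type.  Body size,
#' trophic mode, mobility and external protection are ordered; the rest are
#' categorical.  Used as the default trait structure of the synthetic-data
#' generator and as a template for definitions files.
#'
#' @return A named list of [trait_spec()] objects (length 8).
#' @export
default_trait_specs <- function() {
  specs <- list(
    trait_spec("maximum adult body size", "ordered",
               c("small (~1 mm)", "medium (~10 mm)", "large (~100 mm)",
                 "very large (~1,000 mm)")),
    trait_spec("habitat complexity", "categorical",
               c("does not add complexity", "mat forming (<10 cm)",
                 "bed forming (>10 cm)", "open bush forming",
                 "dense bush forming")),
    trait_spec("trophic mode", "ordered",
               c("symbiont", "bacterivore", "detritivore", "carnivore S",
                 "carnivore O")),
    trait_spec("feeding method", "categorical",
               c("non-feeding", "deposit feeder", "suspension feeder",
                 "predator", "parasite or commensal")),
    trait_spec("relative adult mobility", "ordered",
               c("sessile", "movement restricted", "crawler",
                 "freely mobile")),
    trait_spec("external protection", "ordered",
               c("soft bodied", "moderately protected", "well protected")),
    trait_spec("larval development", "categorical",
               c("lecithotrophic", "planktotrophic", "brooding", "direct")),
    trait_spec("reproductive type", "categorical",
               c("gonochoristic", "hermaphroditic", "asexual"))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

.as_spec_list <- function(specs) {
  if (inherits(specs, "trait_spec")) specs <- list(specs)
  if (!is.list(specs) || !all(vapply(specs, inherits, TRUE, "trait_spec")))
    stop("'specs' must be a list of trait_spec objects")
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(names(specs))) stop("duplicated trait names in 'specs'")
  specs
}

#' Species-by-trait modality table
#'
#' @param assignment a data.frame or character matrix with one row per
#'   species (row names = species identifiers) and one column per trait;
#'   entries are modality labels, `NA` (or `""`) marking a missing value.
#' @param specs list of [trait_spec()] describing each column.
#' @return Object of class `trait_table` with elements `species`, `traits`
#'   and `assignment` (character data.frame, `NA` for missing).
#' @export
trait_table <- function(assignment, specs) {
  specs <- .as_spec_list(specs)
  assignment <- as.data.frame(assignment, stringsAsFactors = FALSE)
  if (nrow(assignment) == 0L) stop("no species in trait table")
  if (is.null(rownames(assignment)) || anyDuplicated(rownames(assignment)))
    stop("assignment must carry unique species row names")
  missing_traits <- setdiff(colnames(assignment), names(specs))
  if (length(missing_traits))
    stop("traits without a definition: ", paste(missing_traits, collapse = ", "))
  assignment <- assignment[, intersect(names(specs), colnames(assignment)),
                           drop = FALSE]
  for (tr in colnames(assignment)) {
    v <- as.character(assignment[[tr]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    bad <- !is.na(v) & !(v %in% specs[[tr]]$levels)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(
        "species '%s', trait '%s': modality '%s' is not among the declared levels",
        rownames(assignment)[i], tr, v[i]))
    }
    assignment[[tr]] <- v
  }
  all_missing <- rowSums(!is.na(as.matrix(assignment))) == 0L
  if (any(all_missing))
    stop("species with no non-missing trait: ",
         paste(rownames(assignment)[all_missing], collapse = ", "))
  structure(list(species = rownames(assignment),
                 traits = colnames(assignment),
                 assignment = assignment),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d species x %d traits (%d missing values)\n",
              length(x$species), length(x$traits),
              sum(is.na(as.matrix(x$assignment)))))
  invisible(x)
}

.norm_name <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

.find_col <- function(df, aliases, what, required = TRUE) {
  nm <- .norm_name(colnames(df))
  hit <- which(nm %in% .norm_name(aliases))
  if (length(hit) == 0L) {
    if (required)
      stop("could not locate a '", what, "' column (tried: ",
           paste(aliases, collapse = ", "), ")")
    return(NA_integer_)
  }
  hit[1L]
}

#' Read trait definitions and species modality assignments
#'
#' The definitions file lists, one row per (trait, modality), the trait name,
#' its type (`ordered`/`categorical`) and the modality label; row order
#' within a trait defines the level order of ordered traits.  The modalities
#' file is either long (`species, trait, modality`) or wide (a species column
#' followed by one column per trait), auto-detected from the header.  Empty
#' cells are missing values.
#'
#' @param definitions_file,modalities_file CSV paths.
#' @return `list(specs = <list of trait_spec>, table = <trait_table>)`.
#' @export
read_trait_table <- function(definitions_file, modalities_file) {
  defs <- utils::read.csv(definitions_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  i_tr <- .find_col(defs, c("trait", "trait_name"), "trait")
  i_ty <- .find_col(defs, c("type", "trait_type", "kind"), "trait type")
  i_mo <- .find_col(defs, c("modality", "level", "modality_label"), "modality")
  specs <- lapply(split(seq_len(nrow(defs)), factor(defs[[i_tr]],
                                                    unique(defs[[i_tr]]))),
                  function(rows) {
                    kind <- tolower(unique(trimws(defs[[i_ty]][rows])))
                    if (length(kind) != 1L)
                      stop("trait '", defs[[i_tr]][rows[1]],
                           "': inconsistent trait type")
                    trait_spec(defs[[i_tr]][rows[1]], kind,
                               defs[[i_mo]][rows])
                  })
  names(specs) <- vapply(specs, `[[`, "", "name")

  mods <- utils::read.csv(modalities_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(mods) == 0L) stop("no species in modalities file")
  nm <- .norm_name(colnames(mods))
  long <- any(nm %in% c("trait", "trait_name")) &&
    any(nm %in% c("modality", "level", "modality_label"))
  if (long) {
    i_sp <- .find_col(mods, c("species", "taxon", "species_name"), "species")
    i_tr <- .find_col(mods, c("trait", "trait_name"), "trait")
    i_mo <- .find_col(mods, c("modality", "level", "modality_label"), "modality")
    if (anyDuplicated(mods[c(i_sp, i_tr)]))
      stop("duplicate (species, trait) rows in modalities file")
    sp <- unique(mods[[i_sp]])
    wide <- matrix(NA_character_, length(sp), length(specs),
                   dimnames = list(sp, names(specs)))
    tr_bad <- setdiff(unique(mods[[i_tr]]), names(specs))
    if (length(tr_bad))
      stop("undeclared traits in modalities file: ",
           paste(tr_bad, collapse = ", "))
    v <- as.character(mods[[i_mo]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    wide[cbind(match(mods[[i_sp]], sp), match(mods[[i_tr]], names(specs)))] <- v
    assignment <- as.data.frame(wide, stringsAsFactors = FALSE)
  } else {
    i_sp <- .find_col(mods, c("species", "taxon", "species_name"), "species",
                      required = FALSE)
    if (is.na(i_sp)) i_sp <- 1L
    if (anyDuplicated(mods[[i_sp]]))
      stop("duplicate species row in modalities file")
    assignment <- mods[, -i_sp, drop = FALSE]
    rownames(assignment) <- mods[[i_sp]]
  }
  list(specs = specs, table = trait_table(assignment, specs))
}

#' Write trait definitions and modality assignments as CSV
#'
#' Inverse of [read_trait_table()]; the long form is the canonical on-disk
#' layout for modalities.
#'
#' @param specs list of [trait_spec()].
#' @param table a [trait_table()].
#' @param definitions_file,modalities_file output CSV paths.
#' @export
write_trait_table <- function(specs, table, definitions_file, modalities_file) {
  specs <- .as_spec_list(specs)
  defs <- do.call(rbind, lapply(specs, function(s)
    data.frame(trait = s$name, type = s$kind, modality = s$levels,
               stringsAsFactors = FALSE)))
  utils::write.csv(defs, definitions_file, row.names = FALSE)
  a <- as.matrix(table$assignment)
  long <- data.frame(
    species = rep(table$species, times = length(table$traits)),
    trait = rep(table$traits, each = length(table$species)),
    modality = as.vector(a), stringsAsFactors = FALSE)
  long$modality[is.na(long$modality)] <- ""
  utils::write.csv(long, modalities_file, row.names = FALSE)
  invisible(c(definitions_file, modalities_file))
}
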