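# Multi-dimensional stress profiling: map extracted entity mentions to
# user facets (gender, degree level, institution tier), cross-tabulate
# documents into mixed-label categories, and estimate per-category
# probability distributions over the five stress features as normalized
# feature-word hit counts.

#' Default facet lexicons
#'
#' Surface-to-facet maps used to interpret extracted entity mentions. The
#' shipped defaults cover the synthetic lexicons; for a real corpus supply
#' your own (see [read_facet_lexicons()]). Matching normalizes to
#' lower-case, collapsed whitespace.
#'
#' @return A list with `sex` (named map surface -> "male"/"female"),
#'   `edu` (surface -> "master"/"doctor") and `world_class` (character
#'   vector of world-class institution surfaces).
#' @export
default_facet_lexicons <- function() {
  list(
    sex = c(male = "male", man = "male", female = "female", woman = "female"),
    edu = c(master = "master", masters = "master", msc = "master",
            phd = "doctor", doctoral = "doctor", doctorate = "doctor"),
    world_class = default_world_class_lexicon()
  )
}

#' Read facet lexicons from a YAML file
#'
#' The file holds three keys: `sex` and `edu` as surface-to-value maps and
#' `world_class` as a list of institution surfaces.
#'
#' @param path YAML file path.
#' @return A lexicon list as in [default_facet_lexicons()].
#' @export
read_facet_lexicons <- function(path) {
  raw <- yaml::read_yaml(path)
  list(sex = unlist(raw$sex), edu = unlist(raw$edu),
       world_class = unlist(raw$world_class))
}

normalize_surface <- function(x) {
  stringr::str_squish(tolower(x))
}

#' Classify an institution surface into a tier
#'
#' @param surface Character vector of ORG mention surfaces.
#' @param world_class_lexicon Character vector of world-class institution
#'   surfaces (normalized matching).
#' @return `"world_class"`, `"non_top_tier"`, or `NA` for empty surfaces.
#' @export
classify_org <- function(surface, world_class_lexicon) {
  s <- normalize_surface(surface)
  lex <- normalize_surface(world_class_lexicon)
  out <- ifelse(s %in% lex, "world_class", "non_top_tier")
  out[!nzchar(s) | is.na(s)] <- NA_character_
  out
}

facet_vote <- function(values) {
  values <- values[!is.na(values)]
  u <- unique(values)
  if (length(u) == 1) u else NA_character_  # absent or conflicting -> unknown
}

#' Derive user facets from extracted entities
#'
#' Maps each document's entity mentions to `sex`, `edu` and `org_tier`
#' facets through the lexicons. A facet with no evidence stays unknown
#' (`NA`); conflicting evidence (e.g. both a male and a female surface)
#' also yields unknown, with a warning count.
#'
#' @param entities A tibble from [extract_entities()] (`post_id`,
#'   `entity_type`, `surface`).
#' @param lexicons A lexicon list (see [default_facet_lexicons()]).
#' @param post_ids Optional character vector of all document ids, so that
#'   documents without any entity appear with all facets unknown.
#' @return A tibble of `post_id`, `sex`, `edu`, `org_tier`.
#' @export
facets_from_entities <- function(entities, lexicons = default_facet_lexicons(),
                                 post_ids = NULL) {
  ids <- post_ids %||% unique(entities$post_id)
  lookup <- function(type, map) {
    e <- entities[entities$entity_type == type, , drop = FALSE]
    vals <- map[normalize_surface(e$surface)]
    tapply(unname(vals), e$post_id, facet_vote)
  }
  sex <- lookup("SEX", lexicons$sex)
  edu <- lookup("EDU", lexicons$edu)
  orge <- entities[entities$entity_type == "ORG", , drop = FALSE]
  org <- tapply(classify_org(orge$surface, lexicons$world_class),
                orge$post_id, facet_vote)
  pick <- function(x) as.vector(x[ids])
  out <- tibble::tibble(
    post_id = as.character(ids),
    sex = pick(sex),
    edu = pick(edu),
    org_tier = pick(org)
  )
  conflicts <- sum(is.na(out$sex) & ids %in% entities$post_id[
    entities$entity_type == "SEX"])
  if (conflicts > 0) {
    warn(paste0(conflicts, " document(s) with conflicting or unmapped SEX",
                " evidence set to unknown"))
  }
  out
}

#' Cross-tabulate documents into mixed-label categories
#'
#' Partitions documents whose two requested facets are both known into the
#' four facet combinations; documents with an unknown facet are excluded
#' and counted in the `"n_excluded"` attribute.
#'
#' @param facets A tibble from [facets_from_entities()].
#' @param dims A pair of facet names: `c("sex", "edu")` or
#'   `c("edu", "org_tier")`.
#' @return `facets` rows with both facets known, plus a `category` column
#'   (`"<dim1>:<dim2>"`).
#' @export
crosstab <- function(facets, dims = c("sex", "edu")) {
  allowed <- list(c("sex", "edu"), c("edu", "org_tier"))
  if (!any(vapply(allowed, identical, logical(1), y = as.character(dims)))) {
    abort("dims must be c('sex','edu') or c('edu','org_tier')")
  }
  known <- !is.na(facets[[dims[1]]]) & !is.na(facets[[dims[2]]])
  out <- facets[known, , drop = FALSE]
  out$category <- paste(out[[dims[1]]], out[[dims[2]]], sep = ":")
  attr(out, "n_excluded") <- sum(!known)
  out
}

#' Per-category stress-feature probability distributions
#'
#' For each category, counts occurrences of each feature's `top_n` words
#' among the category's tokens and normalizes the five hit counts to a
#' probability row. A category with zero hits (or no documents) gets a
#' uniform row flagged `degenerate`.
#'
#' @param tokens Tokenized corpus tibble (`post_id`, `token`).
#' @param categories A tibble from [crosstab()] (`post_id`, `category`).
#' @param feature_map A `"stress_features"` object.
#' @param top_n Words per feature to count (default 10).
#' @return A `"stress_profile"` tibble: `category`, `feature`, `n_docs`,
#'   `hits`, `probability`, `degenerate`.
#' @export
feature_word_probabilities <- function(tokens, categories, feature_map,
                                       top_n = 10) {
  top <- feature_top_words(feature_map, top_n)
  feats <- unique(top$feature)
  cats <- sort(unique(categories$category))
  if (!length(cats)) {
    out <- tibble::tibble(category = character(), feature = character(),
                          n_docs = integer(), hits = numeric(),
                          probability = numeric(), degenerate = logical())
    class(out) <- c("stress_profile", class(out))
    return(out)
  }
  word2feat <- setNames(top$feature, top$token)
  joined <- dplyr::inner_join(tokens, categories[, c("post_id", "category")],
                              by = "post_id")
  rows <- lapply(cats, function(cc) {
    sub <- joined[joined$category == cc, , drop = FALSE]
    hits <- unname(vapply(feats, function(f) {
      sum(sub$token %in% top$token[top$feature == f])
    }, numeric(1)))
    tot <- sum(hits)
    degenerate <- tot == 0
    prob <- if (degenerate) rep(1 / length(feats), length(feats)) else hits / tot
    tibble::tibble(category = cc, feature = feats,
                   n_docs = length(unique(sub$post_id)),
                   hits = hits, probability = prob, degenerate = degenerate)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("stress_profile", class(out))
  out
}

#' Build a stress profile from tokens, facets and a feature map
#'
#' Convenience wrapper: [crosstab()] then [feature_word_probabilities()].
#'
#' @inheritParams feature_word_probabilities
#' @param facets A tibble from [facets_from_entities()].
#' @param dims Facet pair for the cross-tabulation.
#' @return A `"stress_profile"` tibble; excluded-document count in the
#'   `"n_excluded"` attribute.
#' @export
stress_profile <- function(tokens, facets, feature_map,
                           dims = c("sex", "edu"), top_n = 10) {
  cats <- crosstab(facets, dims)
  out <- feature_word_probabilities(tokens, cats, feature_map, top_n)
  attr(out, "n_excluded") <- attr(cats, "n_excluded")
  out
}
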