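#' Type a user by community-follow embeddedness
#'
#' Maps the number of local organizations a user follows to one of five
#' embeddedness types: 1 Unique, 2 Low, 3-9 Moderate, 10-49 High, 50 or more
#' Extreme.
#'
#' @param n_orgs Vector of non-negative follow counts.
#' @return Character vector of user types.
#' @export
categorize_user <- function(n_orgs) {
  if (any(is.na(n_orgs)) || any(n_orgs < 1)) {
    abort("untypeable: users with zero followed organizations carry no community signal.")
  }
  dplyr::case_when(
    n_orgs == 1 ~ "Unique",
    n_orgs == 2 ~ "Low",
    n_orgs <= 9 ~ "Moderate",
    n_orgs <= 49 ~ "High",
    TRUE ~ "Extreme"
  )
}

# Resolve community names against the gazetteer (case-folded exact match).
# Unresolved names are dropped; callers may inspect the `unresolved` attribute.
resolve_communities <- function(communities, gazetteer) {
  idx <- match(tolower(communities), tolower(gazetteer$name))
  res <- gazetteer[idx[!is.na(idx)], , drop = FALSE]
  attr(res, "unresolved") <- communities[is.na(idx)]
  res
}

#' Infer a user's region by social triangulation
#'
#' A declared region is returned as-is with confidence 1. Otherwise the
#' majority region among the user's resolvable followed communities wins,
#' with confidence equal to the majority share. Ties are broken by the most
#' specific community-asset category present in each tied region
#' (see [community_categories()] order), then lexicographically.
#'
#' @param communities Character vector of followed community names.
#' @param gazetteer Gazetteer tibble (name, category, lat, lon, region).
#' @param declared_region Optional declared region name.
#' @return A list with `region` and `confidence`.
#' @export
infer_location <- function(communities, gazetteer, declared_region = NULL) {
  if (!is.null(declared_region) && !is.na(declared_region)) {
    return(list(region = declared_region, confidence = 1))
  }
  res <- resolve_communities(communities, gazetteer)
  if (nrow(res) == 0L) {
    abort("location unknown: no declared region and no resolvable communities.")
  }
  votes <- table(res$region)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    rank <- vapply(top, function(r) {
      min(match(res$category[res$region == r], community_categories()),
          na.rm = TRUE)
    }, numeric(1))
    top <- top[rank == min(rank)]
    top <- sort(top)[1]
  }
  list(region = top, confidence = as.numeric(max(votes)) / nrow(res))
}

#' E-I homophily index of a user's community-follow ties
#'
#' Ties are community-follow edges; a tie is internal when the community's
#' region equals the assigned region. The index is
#' (External - Internal) / (External + Internal), in \[-1, 1\]:
#' -1 fully local, +1 fully external.
#'
#' @param communities Character vector of followed community names.
#' @param assigned_region The user's assigned region.
#' @param gazetteer Gazetteer tibble.
#' @return A one-row tibble with columns `E`, `I`, `value`.
#' @export
ei_index <- function(communities, assigned_region, gazetteer) {
  res <- resolve_communities(communities, gazetteer)
  if (nrow(res) == 0L) {
    abort("undefined E-I score: no resolvable communities.")
  }
  I <- sum(res$region == assigned_region)
  E <- nrow(res) - I
  tibble(E = E, I = I, value = (E - I) / (E + I))
}

#' Geolocate a user table by social triangulation
#'
#' Applies [infer_location()], [categorize_user()] and [ei_index()] across a
#' user table. Users with neither a declared region nor a resolvable
#' community get `NA` with an `unlocatable` flag rather than an error.
#'
#' @param users User tibble with `user_id`, `communities` (list-column) and
#'   optionally `declared_region`.
#' @param gazetteer Gazetteer tibble.
#' @return Tibble with user_id, inferred_region, confidence, user_type,
#'   ei_value, n_resolved, unlocatable.
#' @export
geolocate_users <- function(users, gazetteer) {
  declared <- if ("declared_region" %in% names(users)) users$declared_region
              else rep(NA_character_, nrow(users))
  rows <- lapply(seq_len(nrow(users)), function(i) {
    comms <- users$communities[[i]]
    res <- resolve_communities(comms, gazetteer)
    n_res <- nrow(res)
    type <- if (length(comms) >= 1) categorize_user(length(comms)) else NA_character_
    if (!is.na(declared[i])) {
      region <- declared[i]; conf <- 1
    } else if (n_res >= 1) {
      loc <- infer_location(comms, gazetteer)
      region <- loc$region; conf <- loc$confidence
    } else {
      region <- NA_character_; conf <- NA_real_
    }
    ei <- if (n_res >= 1 && !is.na(region)) {
      ei_index(comms, region, gazetteer)$value
    } else NA_real_
    tibble(user_id = users$user_id[i], inferred_region = region,
           confidence = conf, user_type = type, ei_value = ei,
           n_resolved = n_res, unlocatable = is.na(region))
  })
  bind_rows(rows)
}

#' Evaluate social triangulation against declared locations
#'
#' Restricts to users with both a declared region and at least one
#' resolvable community, infers each one's region from communities alone
#' (ignoring the declaration), and scores the match rate.
#'
#' @param users User tibble (needs `declared_region` and `communities`).
#' @param gazetteer Gazetteer tibble.
#' @return A list with `accuracy`, `n`, and a `details` tibble.
#' @export
evaluate_st <- function(users, gazetteer) {
  eligible <- !is.na(users$declared_region) &
    vapply(users$communities, function(x) length(x) >= 1, logical(1))
  users <- users[eligible, , drop = FALSE]
  details <- lapply(seq_len(nrow(users)), function(i) {
    res <- resolve_communities(users$communities[[i]], gazetteer)
    if (nrow(res) == 0L) return(NULL)
    loc <- infer_location(users$communities[[i]], gazetteer)
    tibble(user_id = users$user_id[i], declared = users$declared_region[i],
           inferred = loc$region, confidence = loc$confidence,
           match = loc$region == users$declared_region[i])
  })
  details <- bind_rows(details)
  if (nrow(details) == 0L) {
    abort("empty evaluation set: no users with declared region and resolvable communities.")
  }
  list(accuracy = mean(details$match), n = nrow(details), details = details)
}
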