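#' Hand-checked worked example
#'
#' A fixed 6-gene x 5-sample expression matrix together with its golden
#' intermediate matrices: Pearson correlation, unsigned adjacency at
#' beta = 2, topological overlap, and degree-normalized zero-diagonal TOM.
#' The goldens were computed once with an independent straight-from-formula
#' triple-loop evaluation and are frozen here; tests compare the package's
#' vectorized implementations against them.
#'
#' @return List `expr`, `beta`, `correlation`, `adjacency`, `tom`,
#'   `norm_tom`.
#' @export
worked_toy <- function() {
  expr <- matrix(c(
    1, 2, 3, 4, 5,
    2, 4, 5, 8, 10,
    5, 4, 3, 2, 1,
    1, 3, 2, 5, 4,
    2, 2, 3, 1, 4,
    10, 8, 9, 6, 7), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
  list(
    expr = expr,
    beta = 2,
    correlation = matrix(c(
      0.99999999999999978, 0.9901475429766744, -0.99999999999999978, 0.79999999999999982, 0.41602514716892181, -0.79999999999999982,
      0.9901475429766744, 1, -0.9901475429766744, 0.84162541153017323, 0.37073364955723559, -0.84162541153017323,
      -0.99999999999999978, -0.9901475429766744, 0.99999999999999978, -0.79999999999999982, -0.41602514716892181, 0.79999999999999982,
      0.79999999999999982, 0.84162541153017323, -0.79999999999999982, 0.99999999999999978, -0.13867504905630726, -0.99999999999999978,
      0.41602514716892181, 0.37073364955723559, -0.41602514716892181, -0.13867504905630726, 0.99999999999999978, 0.13867504905630726,
      -0.79999999999999982, -0.84162541153017323, 0.79999999999999982, -0.99999999999999978, 0.13867504905630726, 0.99999999999999978
    ), nrow = 6, byrow = TRUE),
    adjacency = matrix(c(
      1, 0.98039215686274528, 0.99999999999999956, 0.63999999999999968, 0.17307692307692304, 0.63999999999999968,
      0.98039215686274528, 1, 0.98039215686274528, 0.70833333333333348, 0.13744343891402716, 0.70833333333333348,
      0.99999999999999956, 0.98039215686274528, 1, 0.63999999999999968, 0.17307692307692304, 0.63999999999999968,
      0.63999999999999968, 0.70833333333333348, 0.63999999999999968, 1, 0.019230769230769225, 0.99999999999999956,
      0.17307692307692304, 0.13744343891402716, 0.17307692307692304, 0.019230769230769225, 1, 0.019230769230769225,
      0.63999999999999968, 0.70833333333333348, 0.63999999999999968, 0.99999999999999956, 0.019230769230769225, 1
    ), nrow = 6, byrow = TRUE),
    tom = matrix(c(
      1, 0.83729361734583652, 0.81850872604600278, 0.77734907698359912, 0.37474016524848924, 0.77734907698359912,
      0.83729361734583652, 1, 0.83729361734583652, 0.81055614401005494, 0.36403867102396514, 0.81055614401005494,
      0.81850872604600278, 0.83729361734583652, 1, 0.77734907698359912, 0.37474016524848924, 0.77734907698359912,
      0.77734907698359912, 0.81055614401005494, 0.77734907698359912, 1, 0.23778885961610829, 0.77182259610602666,
      0.37474016524848924, 0.36403867102396514, 0.37474016524848924, 0.23778885961610829, 1, 0.23778885961610829,
      0.77734907698359912, 0.81055614401005494, 0.77734907698359912, 0.77182259610602666, 0.23778885961610829, 1
    ), nrow = 6, byrow = TRUE),
    norm_tom = matrix(c(
      0, 0.23114984933332963, 0.22829952102872381, 0.22347486289598131, 0.15699865127381551, 0.22347486289598131,
      0.23114984933332963, 0, 0.23114984933332963, 0.23063745750997133, 0.15095494536151005, 0.23063745750997133,
      0.22829952102872381, 0.23114984933332963, 0, 0.22347486289598131, 0.15699865127381551, 0.22347486289598131,
      0.22347486289598131, 0.23063745750997133, 0.22347486289598131, 0, 0.10268052661663277, 0.22869727344265078,
      0.15699865127381551, 0.15095494536151005, 0.15699865127381551, 0.10268052661663277, 0, 0.10268052661663277,
      0.22347486289598131, 0.23063745750997133, 0.22347486289598131, 0.22869727344265078, 0.10268052661663277, 0
    ), nrow = 6, byrow = TRUE))
}
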