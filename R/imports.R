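#' @importFrom stats aov TukeyHSD approx coef cor.test cutree dist dnorm
#'   hclust lm nls nls.control optim pnorm ptukey qnorm residuals rgamma
#'   rnorm runif sd setNames var
#' @importFrom utils combn head read.csv tail write.csv write.table
NULL
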