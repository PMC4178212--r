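# Expected hypergeometric upper-tail probabilities computed once with exact
# rational arithmetic (sums of C(K,i)*C(N-K,n-i)/C(N,n) accumulated as
# fractions, converted to double at the end) and frozen here.
hyper_grid <- function() {
  data.frame(
    N = c(100, 200, 24, 24, 30, 200, 150, 50, 17, 200, 10, 60, 45, 120, 80, 33, 199, 12, 150, 96),
    K = c(10, 50, 6, 6, 6, 5, 30, 25, 3, 100, 10, 12, 9, 40, 8, 11, 66, 4, 75, 24),
    n = c(20, 40, 6, 18, 12, 100, 60, 25, 9, 100, 4, 30, 18, 30, 40, 7, 99, 6, 75, 48),
    k = c(8, 15, 6, 6, 4, 5, 10, 20, 2, 60, 4, 0, 9, 19, 1, 5, 40, 3, 50, 12),
    p = c(2.3782749640379137e-05,
          0.035925939842982306,
          7.429641296918184e-06,
          0.1379238610359892,
          0.15311355311355312,
          0.029691605234293292,
          0.8513944292495019,
          2.36388394155159e-05,
          0.5470588235294118,
          0.0035297577475081232,
          1.0,
          1.0,
          5.486574433047251e-05,
          9.64109091916649e-05,
          0.9973469741633432,
          0.027437893956247683,
          0.022166912866376762,
          0.2727272727272727,
          3.881966508516737e-05,
          0.5929767272264892))
}
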