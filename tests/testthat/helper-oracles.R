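# Independent brute-force oracles and frozen reference fixtures.
# These deliberately do NOT share code with the package implementation.

# Literal transcription of the approximate-entropy definition:
# Phi^d(r) = (1/(N-d+1)) sum_i log C_i^d(r), with C_i^d the fraction of
# templates u(j) (j = 1..N-d+1, self included) whose Chebyshev distance
# from u(i) is <= r; ApEn = Phi^m - Phi^(m+1).
oracleApEn <- function(x, m, r) {
  N <- length(x)
  phi <- function(d) {
    nt <- N - d + 1L
    logC <- numeric(nt)
    for (i in seq_len(nt)) {
      ui <- x[i:(i + d - 1L)]
      cnt <- 0L
      for (j in seq_len(nt)) {
        uj <- x[j:(j + d - 1L)]
        if (max(abs(ui - uj)) <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / nt)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

# Literal transcription of the sample-entropy estimator: B counts
# unordered template pairs (i < j, templates starting at 1..N-m) whose
# length-m templates match within r; A the same for length m+1;
# SampEn = -ln(A/B).  Self-matches never enter.
oracleSampEn <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  pairCount <- function(d) {
    s <- 0L
    for (i in seq_len(nt - 1L)) {
      for (j in (i + 1L):nt) {
        if (max(abs(x[i:(i + d - 1L)] - x[j:(j + d - 1L)])) <= r)
          s <- s + 1L
      }
    }
    s
  }
  -log(pairCount(m + 1L) / pairCount(m))
}

# small random recording for IO round-trip tests
randomRecording <- function(nch = 3, n = 40, fs = 100, seed = 1) {
  set.seed(seed)
  eegRecording(matrix(rnorm(nch * n) * 10^sample(-3:3, 1), nrow = nch),
               fs = fs, channels = paste0("ch", seq_len(nch)),
               subjectId = paste0("rt", seed),
               label = sample(c(0L, 1L, NA), 1))
}

# frozen single-level DWT reference outputs (symmetric padding) for
# x = sin(1:n) + 0.05*(1:n), computed with an independent pyramid
# implementation during development
DWT_REFERENCE <- list(
  list(wavelet = "db2", n = 20,
       approx = c(1.3023882952543566, 1.4121494864110586, -0.4867390577416296, -0.2792511775741543, 1.8474933291827438, 0.2704762642648215, -0.1431801044878262, 2.178667351489426, 1.0604115852534903, 0.06982814092695369, 2.417850154954765),
       detail = c(-0.07215366528780046, 0.17084892450057287, -0.5158381010410732, 0.2584798633368829, 0.3007069461635103, -0.5087563520842762, 0.12272774682276108, 0.40661082489057476, -0.46114736379083465, -0.022800791643354697, 0.4979004566931835)),
  list(wavelet = "db2", n = 33,
       approx = c(1.3023882952543566, 1.4121494864110586, -0.4867390577416296, -0.2792511775741543, 1.8474933291827438, 0.2704762642648215, -0.1431801044878262, 2.178667351489426, 1.0604115852534903, 0.06982814092695369, 2.4130870530591553, 1.853937742907609, 0.37660207644091803, 2.5658753273405637, 2.6216395309202674, 0.7865008987074373, 2.604198477999386, 3.830434282943412),
       detail = c(-0.07215366528780046, 0.17084892450057287, -0.5158381010410732, 0.2584798633368829, 0.3007069461635103, -0.5087563520842762, 0.12272774682276108, 0.40661082489057476, -0.46114736379083465, -0.022800791643354697, 0.48012431841714, -0.3768036408739366, -0.16651303211887136, 0.5153913839942188, -0.2624439559468237, -0.29696093991784184, 0.306357783591489, 0.30936085507220235)),
  list(wavelet = "db4", n = 20,
       approx = c(-1.0041137317306854, 0.571496397200691, 1.3088008217344849, 1.2777289244524344, -0.895459745231399, 0.2697302982639128, 1.873685479305488, -0.22591950078618026, 0.3181600716111364, 2.3654778784480186, 0.5187474431205188, 0.4034325951627716, 2.7676049607027284),
       detail = c(-0.1255401633922466, -0.1311199812320209, 0.00787282169515787, 0.26881668724606667, -0.2810647070648006, -0.03488830982593466, 0.31010202659787905, -0.2232076449251958, -0.12432771594036295, 0.3266848162926233, -0.13078780774954468, -0.2272484075923334, 0.2997378639798053)),
  list(wavelet = "db4", n = 33,
       approx = c(-1.0041137317306854, 0.571496397200691, 1.3088008217344849, 1.2777289244524344, -0.895459745231399, 0.2697302982639128, 1.873685479305488, -0.22591950078618026, 0.3181600716111364, 2.3654778784480186, 0.5179754611184427, 0.40886903976270805, 2.7477268537919657, 1.3107635267753648, 0.5684280108018823, 3.023779303587739, 2.118628590023403, 0.8546030689735755, 3.041021195764288, 3.7889862067669577),
       detail = c(-0.1255401633922466, -0.1311199812320209, 0.00787282169515787, 0.26881668724606667, -0.2810647070648006, -0.03488830982593466, 0.31010202659787905, -0.2232076449251958, -0.12432771594036295, 0.3266848162926233, -0.14756998975595603, -0.20386324748015278, 0.31724408081014155, -0.060176993804740064, -0.26715914960062237, 0.28253186372658784, -0.06494003790632309, -0.05943102119622838, -0.10389000979619505, 0.318141927175794)),
  list(wavelet = "db8", n = 20,
       approx = c(0.1132931476889145, -0.04742014063194592, 1.9964878482387545, -0.02584195356995317, -0.5603695169726625, 0.9253498765017464, 1.6184017863936293, 0.3960218418160371, -1.0134326196661883, 1.4002263089300044, 1.201371259550047, -0.6464261849696397, 1.491945611084794, 1.9566250181116702, -0.15665358523761633, 1.5085897681046103, 2.725526617757877),
       detail = c(0.3188798934217309, -0.393708740389109, 0.25946634240632355, -0.2088819397691837, 0.13899791879484705, 0.009851870251277877, -0.13420019946391912, 0.10390511443593631, 0.04689519040883069, -0.1429356847117577, 0.0798195787166802, 0.06610521600228565, -0.11827041643177, 0.008426617140394976, 0.12475720492195833, -0.11583370323745536, -0.028537111772615496)),
  list(wavelet = "db8", n = 33,
       approx = c(0.1132931476889145, -0.04742014063194592, 1.9964878482387545, -0.02584195356995317, -0.5603695169726625, 0.9253498765017464, 1.6184017863936293, 0.3960218418160371, -1.0134326196661883, 1.4002263089300044, 1.2013545276454332, -0.6462378631192758, 1.490920187967251, 1.9603162669214762, -0.16697035834257265, 1.5347075742799072, 2.6461957974314223, 0.42034417909531063, 1.5611013838810386, 3.2374432563909146, 1.1108654187934526, 1.5802112228544565, 3.7258048744082486, 3.080711364557747),
       detail = c(0.3188798934217309, -0.393708740389109, 0.25946634240632355, -0.2088819397691837, 0.13899791879484705, 0.009851870251277877, -0.13420019946391912, 0.10390511443593631, 0.04689519040883069, -0.1429356847117577, 0.07206927563616504, 0.08295288257528978, -0.14111043496851172, 0.034492439656585286, 0.11240259567274977, -0.12804440887438928, -0.02873181823448278, 0.08975598286569883, 0.018749476908950895, -0.09504120049811009, 0.057728455528315625, 0.07605510573751773, -0.144086657861312, 0.05140478864270894))
)
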