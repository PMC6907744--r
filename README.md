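# swarmecho

Monte-Carlo simulation of the echoes an echolocating bat receives from a
swarm of insects.

Many of the insects bats eat are individually too small to detect by sonar
beyond a couple of metres — but they swarm. A swarm returns a louder echo,
and it returns a *stochastic* one: the phasor contributions of its members
interfere, carving unpredictable peaks and troughs into the echo spectrum.
`swarmecho` is for sensory ecologists and bioacousticians who want to
quantify both effects: how echo level grows with swarm size, and how much
signal bandwidth a bat needs so that, whatever the momentary swarm
configuration, its call always straddles a spectral peak.

## The model

A swarm realization is a set of *N* point scatterers on a jittered cubic
voxel lattice of pitch *R* (spherical fill; the four standard conditions
are R = 15/35/60/120 mm with 3D jitter SD 6/15/26/52 mm). With the
emitter/receiver at distance *d<sub>i</sub>* from target *i* (round trip
*D<sub>i</sub>* = 2 *d<sub>i</sub>*), the received spectrum on a 12–80 kHz
grid is the coherent sum

P(f) = Σ<sub>i</sub> r<sub>i</sub>(f) · a<sub>i</sub> ·
exp(−j(2π·frac(D<sub>i</sub>/λ) + π)),   λ = c/f,

with spherical-spreading amplitudes a<sub>i</sub> = 10^(TS/20) ·
(d<sub>ref</sub>/d<sub>i</sub>) (target strength TS = −60 dB at
d<sub>ref</sub> = 0.1 m) and r<sub>i</sub> the reflector response at the
target's aspect angle — either an ideal point reflector or a synthetic
insect table with a Rayleigh-like rising frequency response. On top of the
echo engine sit Monte-Carlo analyses (levels vs *N*, percentile-guaranteed
level vs bandwidth, spectral-trough statistics, pulses-vs-bandwidth) and a
closed-form sonar-equation module (detection ranges under atmospheric
absorption, temporal-integration gain).

## Worked example

```r
library(swarmecho)

# one realization of a 16-insect swarm at 35 mm spacing
sw <- generate_swarm(swarm_spec(16, 35, seed = 2), realization_id = 1)
swarm_diameter(sw)          # 0.111  (m)

sp <- echo_spectrum(sw)     # bat at 2 m, point reflectors, 12-80 kHz
spectrum_stats(sp)
#    peak_db    mean_db
#  -69.27713  -76.53380

# what a 500 Hz-wide call ending at 25 kHz could receive from this swarm,
# vs the full 12.5 kHz band
band_max(sp, 25000, 500)    # -71.55 dB
band_max(sp, 25000, 12500)  # -70.26 dB

# detection ranges: one midge vs a swarm of 300, 25 kHz call (0.5 dB/m)
detection_range(1,   sonar_params(), 0.5)   # 2.72 m
detection_range(300, sonar_params(), 0.5)   # 8.24 m

# a swarm's depth stretches an 8 ms pulse; perfect integration gain
integration_gain(8.9, 8)    # 0.93 dB
```

This realization happens to be kind to a narrowband caller: its 500 Hz
band lands within 1.3 dB of the best this spectral region offers. Across
realizations that penalty is a lottery — the 75%-guaranteed level at
500 Hz runs ~8 dB below the broadband plateau, and the worst draws lose
considerably more — which is exactly why broadband calls pay off. The
300-strong swarm, meanwhile, is detectable three times farther away than a
single insect.

The full analyses live in `analysis/01_swarm_geometry.R` …
`analysis/06_detection.R`; each is a thin driver over the package functions
that prints what it found and writes tidy CSVs under `results/`.

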