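# Synthetic ECG-like regime definitions.
#
# Each regime pairs an ARMA mean truth with an EGARCH variance truth for the
# noise process riding on a quasi-periodic beat baseline; the beat train is
# what makes the mean nonstationary, while the noise carries the volatility
# clustering. The apnea-like regime has stronger volatility persistence and
# shock response than the normal-like regime, making the two noise processes
# separable by the ARCH-LM statistic at segment length (on raw segments the
# statistic is dominated by the beat train, as with real ECG, where every
# segment rejects). The homoskedastic control zeroes all dynamics (and the
# beat baseline) so its segments carry the exact null of the
# heteroskedasticity tests.
#
# egarch_alpha0 is chosen as (1 - persist) * log(target variance) so each
# regime's unconditional noise variance is 0.01 (i.e. 0.1 mV noise under
# 0.9 mV beats).

[apnea_like]
label: apnea
baseline_amplitude: 0.9
beat_rate_hz: 1.1
beat_jitter_sd: 0.06
beat_width_s: 0.012
mean_ar: 0.5
mean_ma: 0.3
mean_d: 0
egarch_shock: 1
egarch_persist: 0.95
egarch_theta: -0.10
egarch_lambda: 0.35
egarch_alpha0: -0.23025851

[normal_like]
label: normal
baseline_amplitude: 0.9
beat_rate_hz: 1.1
beat_jitter_sd: 0.06
beat_width_s: 0.012
mean_ar: 0.5
mean_ma: 0.3
mean_d: 0
egarch_shock: 1
egarch_persist: 0.80
egarch_theta: -0.05
egarch_lambda: 0.15
egarch_alpha0: -0.92103404

[homoskedastic_control]
label: unknown
baseline_amplitude: 0
beat_rate_hz: 0
beat_jitter_sd: 0
beat_width_s: 0.012
mean_ar: 0
mean_ma: 0
mean_d: 0
egarch_shock: 0
egarch_persist: 0
egarch_theta: 0
egarch_lambda: 0
egarch_alpha0: -4.60517019
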