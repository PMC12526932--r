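# Example device profiles: five consumer Android models plus an idealized
# zero-latency control device.
#
# Sampling rates and the two audio feature flags are declared hardware
# characteristics of the models named.  The latency mean/sd entries are
# SYNTHETIC stand-ins chosen to be consistent with each device's declared
# audio round-trip latency (one-way ~ half the round trip) -- they make the
# simulators produce plausible streams and are not bench measurements.
#
# Latency fields are [mean_ms, sd_ms].

perfect:
  name: Perfect reference device
  accel_rate_hz: 500
  touch_rate_hz: 120
  audio_latency_ms: [0, 0]
  vib_latency_ms: [0, 0]
  touch_pipeline_latency_ms: [0, 0]
  accel_noise_sd: 0
  has_low_latency: true
  has_pro: true

pixel_2_xl:
  name: Google Pixel 2 XL
  accel_rate_hz: 500
  touch_rate_hz: 120
  audio_latency_ms: [15, 2]    # synthetic; declared round-trip ~30 ms
  vib_latency_ms: [10, 3]
  touch_pipeline_latency_ms: [12, 2]
  accel_noise_sd: 0.05
  has_low_latency: true
  has_pro: true

fairphone_4:
  name: Fairphone 4 5G
  accel_rate_hz: 400
  touch_rate_hz: 60
  audio_latency_ms: [30, 3]    # synthetic; declared round-trip ~60 ms
  vib_latency_ms: [12, 4]
  touch_pipeline_latency_ms: [14, 3]
  accel_noise_sd: 0.05
  has_low_latency: true
  has_pro: true

samsung_a15:
  name: Samsung Galaxy A15
  accel_rate_hz: 320
  touch_rate_hz: 90
  audio_latency_ms: [40, 8]    # synthetic; declared round-trip ~80 ms
  vib_latency_ms: [15, 6]
  touch_pipeline_latency_ms: [16, 4]
  accel_noise_sd: 0.08
  has_low_latency: true
  has_pro: false

motorola_g24:
  name: Motorola G24
  accel_rate_hz: 400
  touch_rate_hz: 90
  audio_latency_ms: [55, 14]   # synthetic; declared round-trip ~110 ms
  vib_latency_ms: [18, 6]
  touch_pipeline_latency_ms: [16, 4]
  accel_noise_sd: 0.08
  has_low_latency: true
  has_pro: false

samsung_a20e:
  name: Samsung Galaxy A20e
  accel_rate_hz: 100
  touch_rate_hz: 120
  audio_latency_ms: [60, 15]   # synthetic; declared round-trip ~120 ms
  vib_latency_ms: [20, 8]
  touch_pipeline_latency_ms: [18, 5]
  accel_noise_sd: 0.1
  has_low_latency: false
  has_pro: false
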