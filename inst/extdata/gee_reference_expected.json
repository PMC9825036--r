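{
 "terms": [
  "(Intercept)",
  "a_lag",
  "v_lag",
  "x1",
  "x2",
  "x3"
 ],
 "beta": [
  11.269463559556687,
  -0.7981823125791747,
  0.889051306575021,
  -1.802671031394199,
  2.1657391082750626,
  6.274772250362
 ],
 "robust_se": [
  0.7991457073852269,
  0.3614431129778969,
  0.5679871888437407,
  0.7062595006992789,
  0.6170177278127373,
  11.141584172135662
 ]
}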