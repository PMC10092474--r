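# Two-parameter normal-ogive (probit) item parameter estimates for the
# IDQ and IAQ from the instruments' initial validation study
# (UK community sample, N = 2058; binary endorsement recodes, response >= 3).
# a = discrimination (probit slope on theta), b = difficulty (theta at 50%
# endorsement); se_a, se_b = reported standard errors.
instrument,item,a,se_a,b,se_b
IDQ,1,2.864,0.225,1.190,0.040
IDQ,2,3.127,0.252,1.121,0.038
IDQ,3,2.408,0.176,1.204,0.042
IDQ,4,2.911,0.232,1.154,0.039
IDQ,5,3.159,0.266,1.159,0.039
IDQ,6,2.035,0.162,1.511,0.054
IDQ,7,1.972,0.141,1.267,0.046
IDQ,8,2.256,0.171,1.307,0.045
IDQ,9,2.204,0.147,0.980,0.038
IAQ,1,3.369,0.295,1.044,0.036
IAQ,2,3.291,0.279,0.977,0.035
IAQ,3,3.364,0.295,1.107,0.037
IAQ,4,2.237,0.177,1.359,0.047
IAQ,5,3.489,0.307,1.117,0.037
IAQ,6,2.433,0.180,1.143,0.040
IAQ,7,2.298,0.168,1.174,0.042
IAQ,8,1.571,0.102,1.077,0.045
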