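# Observed item response distributions for the IDQ and IAQ in the
# instruments' initial validation study (UK community sample, N = 2058).
# p0..p4 = proportion of respondents in each response category
# (0 Never ... 4 Every day); pct_endorsed = percent responding 3 or 4;
# item_total_r = Pearson item-total correlation (item included in total).
# Used as calibration targets for the synthetic-cohort generator's
# graded-response cutpoints.
instrument,item,p0,p1,p2,p3,p4,pct_endorsed,item_total_r
IDQ,1,0.502,0.266,0.101,0.085,0.046,13.1,0.86
IDQ,2,0.496,0.261,0.100,0.097,0.046,14.3,0.88
IDQ,3,0.511,0.247,0.109,0.087,0.046,13.3,0.86
IDQ,4,0.603,0.172,0.088,0.087,0.050,13.8,0.87
IDQ,5,0.600,0.174,0.091,0.078,0.056,13.5,0.88
IDQ,6,0.749,0.096,0.068,0.058,0.030,8.7,0.77
IDQ,7,0.530,0.234,0.107,0.085,0.045,12.9,0.81
IDQ,8,0.613,0.174,0.097,0.084,0.032,11.6,0.83
IDQ,9,0.426,0.270,0.118,0.113,0.073,18.6,0.80
IAQ,1,0.375,0.359,0.107,0.098,0.061,15.8,0.86
IAQ,2,0.373,0.347,0.105,0.109,0.066,17.5,0.87
IAQ,3,0.473,0.276,0.107,0.098,0.047,14.4,0.90
IAQ,4,0.611,0.189,0.092,0.070,0.037,10.7,0.82
IAQ,5,0.496,0.254,0.108,0.091,0.051,14.1,0.89
IAQ,6,0.494,0.258,0.103,0.093,0.052,14.5,0.86
IAQ,7,0.431,0.308,0.120,0.093,0.048,14.1,0.85
IAQ,8,0.393,0.310,0.116,0.118,0.064,18.2,0.75
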