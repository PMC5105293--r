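# NHANES-III adult spirometry reference coefficients (version: nhanes3-adult-1.0)
# Source: Hankinson JL, Odencrantz JR, Fedan KB. Spirometric reference values from
#   a sample of the general U.S. population. Am J Respir Crit Care Med 1999;159:179-187.
# Predicted value = b0 + b_age*age + b_age2*age^2 + b_ht2*height_cm^2
#   (fev1, fvc in litres; ratio in percent, b_ht2 = 0 for ratio rows).
# lln_b0 replaces b0 to obtain the lower limit of normal (5th percentile).
#   For the ratio rows lln_b0 is the published LLN intercept; for the volume rows it is
#   derived as b0 - 1.645*resid_sd under homoscedastic residuals (resid_sd in litres).
# age_min is the lower bound of the adult equation segment; age_max_deriv is the upper
#   age of the derivation sample (older ages are extrapolated with a warning).
quantity	sex	ethnicity	age_min	age_max_deriv	b0	b_age	b_age2	b_ht2	lln_b0	resid_sd
fev1	male	caucasian	20	80	0.5536	-0.01303	-0.000172	0.00014098	-0.12085	0.41
fev1	male	african_american	20	80	0.3411	-0.02309	0	0.00013194	-0.33335	0.41
fev1	male	mexican_american	20	80	0.6306	-0.02928	0	0.00015104	-0.04385	0.41
fev1	female	caucasian	18	80	0.4333	-0.00361	-0.000194	0.00011496	-0.10955	0.33
fev1	female	african_american	18	80	0.3433	-0.01283	-0.000097	0.00013497	-0.19955	0.33
fev1	female	mexican_american	18	80	0.4529	-0.01178	-0.000077	0.00012154	-0.08995	0.33
fvc	male	caucasian	20	80	-0.1933	0.00064	-0.000269	0.00018642	-1.0816	0.54
fvc	male	african_american	20	80	-0.1517	-0.01821	0	0.00016643	-1.04	0.54
fvc	male	mexican_american	20	80	0.2376	-0.00891	-0.000182	0.00017823	-0.6507	0.54
fvc	female	caucasian	18	80	-0.356	0.0187	-0.000382	0.00014815	-0.99755	0.39
fvc	female	african_american	18	80	-0.3039	0.00536	-0.000265	0.00013606	-0.94545	0.39
fvc	female	mexican_american	18	80	0.121	0.00307	-0.000237	0.00014246	-0.52055	0.39
ratio	male	caucasian	20	80	88.066	-0.2066	0	0	78.388	NA
ratio	male	african_american	20	80	89.239	-0.1828	0	0	78.822	NA
ratio	male	mexican_american	20	80	90.024	-0.2186	0	0	80.925	NA
ratio	female	caucasian	18	80	90.809	-0.2125	0	0	81.015	NA
ratio	female	african_american	18	80	91.655	-0.2039	0	0	80.978	NA
ratio	female	mexican_american	18	80	92.36	-0.2248	0	0	83.044	NA
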