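# Indicator codes filling the four estimator roles, per financial year.
# General-population cessation codes (hence a general prevalence estimate)
# exist only from 2012/13; the general status role is retired in 2014/15.
"2006/2007":
  status_general: RECORDS22
  status_chronic: SM01
  cessation_chronic: SM02
"2007/2008":
  status_general: RECORDS22
  status_chronic: SM01
  cessation_chronic: SM02
"2008/2009":
  status_general: RECORDS23
  status_chronic: SM03
  cessation_chronic: SM04
"2009/2010":
  status_general: RECORDS23
  status_chronic: SM03
  cessation_chronic: SM04
"2010/2011":
  status_general: RECORDS23
  status_chronic: SM03
  cessation_chronic: SM04
"2011/2012":
  status_general: RECORDS23
  status_chronic: SM03
  cessation_chronic: SM04
"2012/2013":
  status_general: SM07
  cessation_general: SM08
  status_chronic: SM05
  cessation_chronic: SM06
"2013/2014":
  status_general: SMOK001
  cessation_general: SMOK004
  status_chronic: SMOK002
  cessation_chronic: SMOK005
"2014/2015":
  cessation_general: SMOK004
  status_chronic: SMOK002
  cessation_chronic: SMOK005
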