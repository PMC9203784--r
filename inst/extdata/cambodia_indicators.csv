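goal_id,indicator,year,value,increase_is_progress
1,population below national poverty line (%),2003,50,FALSE
1,population below national poverty line (%),2006,45,FALSE
1,population below national poverty line (%),2010,22.1,FALSE
1,population below national poverty line (%),2014,14,FALSE
2,prevalence of undernourishment (%),2001,24,FALSE
2,prevalence of undernourishment (%),2005,17,FALSE
2,prevalence of undernourishment (%),2010,13,FALSE
2,prevalence of undernourishment (%),2015,8.9,FALSE
2,prevalence of undernourishment (%),2019,6.2,FALSE
3,under-five mortality rate (per 1000 live births),2000,106,FALSE
3,under-five mortality rate (per 1000 live births),2005,65,FALSE
3,under-five mortality rate (per 1000 live births),2010,44,FALSE
3,under-five mortality rate (per 1000 live births),2015,32,FALSE
3,under-five mortality rate (per 1000 live births),2019,27,FALSE
3,children under 5 moderately or severely stunted (%),2000,49,FALSE
3,children under 5 moderately or severely stunted (%),2005,43,FALSE
3,children under 5 moderately or severely stunted (%),2010,39.8,FALSE
3,children under 5 moderately or severely stunted (%),2014,32,FALSE
3,children under 5 moderately or severely wasted (%),2000,17,FALSE
3,children under 5 moderately or severely wasted (%),2005,8.5,FALSE
3,children under 5 moderately or severely wasted (%),2010,11,FALSE
3,children under 5 moderately or severely wasted (%),2014,9.7,FALSE
4,completion rate at primary level (%),2000,34,TRUE
4,completion rate at primary level (%),2005,59,TRUE
4,completion rate at primary level (%),2010,71,TRUE
4,completion rate at primary level (%),2014,72,TRUE
4,completion rate at secondary level (%),2000,17,TRUE
4,completion rate at secondary level (%),2005,27,TRUE
4,completion rate at secondary level (%),2010,37,TRUE
4,completion rate at secondary level (%),2014,41,TRUE
5,seats held by women in legislation institutions (%),2000,8.2,TRUE
5,seats held by women in legislation institutions (%),2005,9.8,TRUE
5,seats held by women in legislation institutions (%),2010,21,TRUE
5,seats held by women in legislation institutions (%),2015,20,TRUE
5,seats held by women in legislation institutions (%),2019,20,TRUE
6,population using safely managed drinking water (%),2000,17,TRUE
6,population using safely managed drinking water (%),2005,19,TRUE
6,population using safely managed drinking water (%),2010,22,TRUE
6,population using safely managed drinking water (%),2015,25,TRUE
6,population using safely managed drinking water (%),2019,27,TRUE
6,population with basic handwashing facilities (%),2010,63,TRUE
6,population with basic handwashing facilities (%),2015,67,TRUE
6,population with basic handwashing facilities (%),2019,73,TRUE
7,population with access to electricity (%),2000,17,TRUE
7,population with access to electricity (%),2005,21,TRUE
7,population with access to electricity (%),2010,31,TRUE
7,population with access to electricity (%),2015,69,TRUE
7,population with access to electricity (%),2019,93,TRUE
8,GDP per capita (current US$),2000,301,TRUE
8,GDP per capita (current US$),2005,474,TRUE
8,GDP per capita (current US$),2010,785,TRUE
8,GDP per capita (current US$),2015,1162,TRUE
8,GDP per capita (current US$),2019,1643,TRUE
9,population covered by at least a 3G mobile network (%),2009,43,TRUE
9,population covered by at least a 3G mobile network (%),2015,70,TRUE
9,population covered by at least a 3G mobile network (%),2019,85,TRUE
10,Gini index disposable income (0-100),2005,37,FALSE
10,Gini index disposable income (0-100),2010,37,FALSE
10,Gini index disposable income (0-100),2015,36,FALSE
11,urban population living in slums (%),2000,79,FALSE
11,urban population living in slums (%),2014,55,FALSE
11,urban population living in slums (%),2018,45,FALSE
12,domestic material consumption per capita (tonnes),2000,2.2,FALSE
12,domestic material consumption per capita (tonnes),2005,2.7,FALSE
12,domestic material consumption per capita (tonnes),2010,6.1,FALSE
12,domestic material consumption per capita (tonnes),2015,4.9,FALSE
12,domestic material consumption per capita (tonnes),2017,5.3,FALSE
13,domestic fossil fuel consumption per capita (tonnes),2000,0.1,FALSE
13,domestic fossil fuel consumption per capita (tonnes),2005,0.1,FALSE
13,domestic fossil fuel consumption per capita (tonnes),2010,0.1,FALSE
13,domestic fossil fuel consumption per capita (tonnes),2015,0.2,FALSE
13,domestic fossil fuel consumption per capita (tonnes),2017,0.2,FALSE
14,sustainable fisheries as a proportion of GDP (%),2011,1.1,TRUE
14,sustainable fisheries as a proportion of GDP (%),2015,0.8,TRUE
14,sustainable fisheries as a proportion of GDP (%),2017,0.6,TRUE
15,forest area as a proportion of total land area (%),2000,61,TRUE
15,forest area as a proportion of total land area (%),2005,60,TRUE
15,forest area as a proportion of total land area (%),2010,50,TRUE
15,forest area as a proportion of total land area (%),2015,46,TRUE
16,voice and accountability (-2.5 weak to 2.5 strong),2000,-0.8,TRUE
16,voice and accountability (-2.5 weak to 2.5 strong),2005,-1.0,TRUE
16,voice and accountability (-2.5 weak to 2.5 strong),2010,-0.9,TRUE
16,voice and accountability (-2.5 weak to 2.5 strong),2015,-1.1,TRUE
16,voice and accountability (-2.5 weak to 2.5 strong),2019,-1.2,TRUE
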