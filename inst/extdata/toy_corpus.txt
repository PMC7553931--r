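HOW DO YOU LIKE THE PASTA YOU EAT
I WANT SOMETHING TO DRINK
COULD YOU PREPARE SOME HOT CHOCOLATE
MY MOTHER BAKES REALLY NICE CAKES
THE WEATHER IN GERMANY IS MOSTLY COLD
WE WILL MAKE A STUDY ROUND TOMORROW
YOU SPEAK ENGLISH VERY WELL
WHAT DO YOU DO FOR WORK
NEXT TIME WE WILL ORDER THE BIG BURGER
WE WILL GO ON HOLIDAYS NEXT MONTH
I WOULD LIKE TO EAT SOMETHING
ONE APPLE A DAY MAKES THE DOCTOR AWAY
I TAKE YOGA AND PILATES CLASSES
WOULD YOU MIND IF I GO EARLIER TONIGHT
AT NIGHT OR IN THE MORNING
WE LIVE IN THE BEST OF ALL POSSIBLE WORLDS
I WOULD LIKE SOME COFFEE
YOU CANNOT STEP TWICE IN THE SAME RIVER
WHAT ARE YOU GOING TO DO TODAY
LIBERTY CONSISTS IN DOING WHAT ONE DESIRES
I WILL TRY TO MAKE IT RIGHT THIS TIME
HOW ABOUT THE KOREAN RESTAURANT
WHAT ARE YOU PLANNING TO DO TODAY
WE MUST TAKE CARE OF OUR PLANET
PLEASE BRING ALL YOUR DOCUMENTS BY TOMORROW
I NEED TO GO TO THE STORE TOO
DO YOU FEEL COMFORTABLE ON THAT CHAIR
I AM ONLY HAPPY WHEN IT RAINS
HAVING A HEALTHY LIFE IS IMPORTANT
THE SCIENCE OF TODAY IS THE TECHNOLOGY OF TOMORROW
MAN IS THE MEASURE OF ALL THINGS
WOULD YOU LIKE TO GO NOW OR LATER
I WOULD LIKE TO COME WITH YOU
LEARNING IS THE BEGINNING OF WEALTH
ALWAYS GO WHERE THE PEOPLE DANCE
DO NOT JUDGE MY PAST I DO NOT LIVE THERE
IT IS NEVER GOOD TO BE CRUEL WITH OTHERS
USE WHAT YOU HAVE AND DO WHAT YOU CAN
NOTHING REALLY SEEMS TO BE EASY
YESTERDAY I FOUND MONEY IN MY PANTS
KNOWING IS NOT ENOUGH WE MUST APPLY
YOU ARE NEVER TOO OLD TO SET ANOTHER GOAL
YOU SHOULD BE DANCING SALSA NOW
WOULD YOU GO TO THE CINEMA WITH ME
SET YOUR GOALS HIGH AND NEVER STOP
PROBLEMS ARE NOT STOP SIGNS THEY ARE GUIDELINES
IT ALWAYS SEEMS IMPOSSIBLE TILL IT IS DONE
MUSIC IS MOTIVATIONAL AND MAKES YOU RELAX
TO SUCCEED YOU MUST FIRST BELIEVE
FOLLOW YOUR INNER MOONLIGHT AND DO NOT HIDE
BE GENTLE WITH ALL AND STERN WITH YOURSELF
MAY THE FORCE BE WITH YOU ON MONDAY
SHE LIKES CHOCOLATE ICE CREAM
THE BANANAS HERE DO NOT TASTE DELICIOUS
THE WINTER TIME IS REALLY COLD AND HUMID
I WILL MAKE HIM AN OFFER HE CAN NOT REFUSE
MY NAME IS BOND JUST BOND
I WOULD LIKE TO GET SOME SUNSHINE EVERYDAY
THE QUICK BROWN FOX JUMPS OVER THE LAZY DOG
THE SUN RISES IN THE EAST EVERY MORNING
PLEASE OPEN THE WINDOW A LITTLE BIT
THE CHILDREN PLAY IN THE GARDEN AFTER SCHOOL
SHE READS A NEW BOOK EVERY SINGLE WEEK
WE WATCHED A GREAT MOVIE LAST NIGHT
THE TRAIN LEAVES THE STATION AT NOON
HE DRINKS A GLASS OF WATER WITH EVERY MEAL
THE CAT SLEEPS ON THE WARM SOFA
MY FRIEND LIVES NEAR THE OLD BRIDGE
THE COFFEE SHOP ON THE CORNER IS OPEN
I LIKE TO WALK ALONG THE RIVER
THE STUDENTS WRITE THEIR NOTES CAREFULLY
THE TEACHER EXPLAINS THE LESSON AGAIN
WE COOK DINNER TOGETHER ON SUNDAYS
THE BIRDS SING EARLY IN THE MORNING
SHE PLAYS THE PIANO VERY WELL
THE GARDEN LOOKS BEAUTIFUL IN SPRING
PLEASE CLOSE THE DOOR WHEN YOU LEAVE
THE PHONE RINGS IN THE OTHER ROOM
HE FORGOT HIS KEYS AT THE OFFICE
THE BAKERY SELLS FRESH BREAD EVERY DAY
WE VISITED THE MUSEUM LAST SUMMER
THE DOG RUNS AROUND THE PARK
I WRITE A LETTER TO MY GRANDMOTHER
THE MOON SHINES BRIGHT OVER THE LAKE
SHE WEARS A RED COAT IN WINTER
THE SHOP CLOSES AT EIGHT IN THE EVENING
WE PLANT TOMATOES IN THE GARDEN
THE BUS STOPS IN FRONT OF THE LIBRARY
HE REPAIRS OLD CLOCKS IN HIS FREE TIME
THE SOUP NEEDS A LITTLE MORE SALT
I FOUND A NICE PLACE TO READ
THE RAIN FELL SOFTLY ON THE ROOF
SHE PAINTS PICTURES OF THE SEA
WE LISTEN TO MUSIC IN THE CAR
THE BABY SMILES AT EVERYONE
THE LETTER ARRIVED AFTER TWO WEEKS
HE CLIMBS THE STAIRS TO THE TOP FLOOR
THE MARKET IS BUSY ON SATURDAY MORNING
I KEEP MY PHOTOS IN A SMALL BOX
THE LIGHT TURNS GREEN AND WE GO
SHE TELLS THE BEST STORIES AT DINNER
THE SNOW COVERS THE WHOLE VALLEY
WE SHARE A PIZZA AFTER THE GAME
THE CLOCK ON THE WALL IS SLOW
HE CARRIES THE BAGS INTO THE HOUSE
THE FLOWERS NEED WATER EVERY DAY
I MEET MY FRIENDS AT THE CAFE
THE ROAD TO THE VILLAGE IS NARROW
SHE SINGS A QUIET SONG TO THE BABY
WE WAIT FOR THE SUMMER HOLIDAYS
THE FISH SWIM IN THE CLEAR WATER
HE OPENS THE SHOP EARLY ON MONDAY
THE STARS APPEAR AFTER SUNSET
I LEARN A NEW WORD EVERY DAY
THE KITCHEN SMELLS OF FRESH COOKIES
WE TAKE THE TRAIN TO THE CITY
THE WIND MOVES THE TALL TREES
SHE FINDS THE ANSWER IN THE BOOK
THE GAME STARTS AT SEVEN TONIGHT
HE GIVES THE DRIVER THE ADDRESS
THE BRIDGE CROSSES THE WIDE RIVER
I REMEMBER MY FIRST DAY AT SCHOOL
THE TEA IS TOO HOT TO DRINK
WE CLEAN THE HOUSE BEFORE THE PARTY
THE HORSE EATS GRASS IN THE FIELD
SHE BUYS FRESH FRUIT AT THE MARKET
THE MUSIC PLAYS UNTIL MIDNIGHT
HE READS THE NEWS EVERY MORNING
THE SHIP SAILS AT DAWN TOMORROW
I DRAW A MAP OF THE OLD TOWN
THE LAMP ON THE DESK IS BROKEN
WE WALK HOME UNDER THE STARS
THE ANSWER TO YOUR QUESTION IS SIMPLE
SHE KEEPS HER PROMISES EVERY TIME
THE WATER IN THE LAKE IS COLD
HE PLANS A TRIP TO THE MOUNTAINS
THE STORY ENDS WITH A SURPRISE
I THANK YOU FOR YOUR KIND HELP
THE DOOR TO THE CELLAR IS LOCKED
WE ENJOY THE QUIET OF THE EVENING
THE APPLES FALL FROM THE TREE
SHE TEACHES THE CHILDREN TO SWIM
THE FIRE BURNS WARM IN THE NIGHT
HE SAVES A LITTLE MONEY EACH MONTH
THE PATH LEADS THROUGH THE FOREST
I TRY TO DO MY BEST EVERY DAY
THE TABLE IS SET FOR SIX GUESTS
WE REACH THE TOP BEFORE NOON
THE BELL RINGS AT THE END OF CLASS
SHE ANSWERS EVERY LETTER SHE GETS
THE MILK IS FRESH FROM THE FARM
HE TELLS THE TRUTH EVEN WHEN IT HURTS
THE CITY LIGHTS SHINE ACROSS THE BAY
I PACK MY BAG THE NIGHT BEFORE
THE CONCERT HALL IS FULL TONIGHT
WE FEED THE DUCKS AT THE POND
THE SUMMER RAIN IS WARM AND SOFT
SHE WRITES HER NAME ON THE LIST
THE ENGINE STARTS ON THE FIRST TRY
HE WAITS FOR THE LAST BUS HOME
THE GARDEN GATE SQUEAKS IN THE WIND
I CHOOSE THE WINDOW SEAT ON TRAINS
THE BREAD IS STILL WARM FROM THE OVEN
WE COUNT THE WAVES ON THE BEACH
THE LIBRARY IS QUIET IN THE AFTERNOON
SHE HOLDS THE UMBRELLA OVER US BOTH
THE FIRST SNOW MAKES EVERYTHING NEW
HE FIXES THE FENCE BEHIND THE HOUSE
THE KETTLE WHISTLES IN THE KITCHEN
I SAVE THE BEST PART FOR LAST
THE MORNING AIR IS COOL AND CLEAR
WE TELL JOKES AROUND THE FIRE
THE LAST LEAF FALLS IN NOVEMBER
SHE SMILES WHEN SHE HEARS THE SONG
THE OLD CLOCK STRIKES TWELVE AT NOON
HE BRINGS FLOWERS EVERY FRIDAY
THE SEA IS CALM BEFORE THE STORM
I FOLLOW THE RIVER TO THE SEA
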